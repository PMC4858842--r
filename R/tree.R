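#' Default Oryza/Leersia species tree
#'
#' An 11-taxon rooted tree covering the cultivated rices (*O. sativa* ssp.
#' japonica and indica), their wild Asian relatives (*O. nivara*,
#' *O. rufipogon*), the African clade (*O. glaberrima*, *O. barthii*), the
#' remaining AA-genome species (*O. glumaepatula*, *O. meridionalis*), the
#' BB-genome *O. punctata*, the basal *O. brachyantha* and the outgroup
#' *Leersia perrieri*.  Branch lengths are divergence times in million
#' years (MY), calibrated so that the Asian crown sits at 0.8 MY, the
#' AA-genome crown at 2.5 MY, the AA+BB split at 6.8 MY and the root at
#' 26 MY; internal nodes carry labels used as branch identifiers
#' throughout (the branch *above* a node is named after that node; terminal
#' branches are named after their tip).
#'
#' @return An [ape::read.tree] `phylo` object with node labels.
#' @export
oryza_tree <- function() {
  nwk <- paste0(
    "((((((((japonica:0.4,nivara:0.4)JapNiv:0.4,",
    "(indica:0.4,rufipogon:0.4)IndRuf:0.4)Asian:1.0,",
    "(glaberrima:0.4,barthii:0.4)Afr:1.4)AsAf:0.3,",
    "glumaepatula:2.1)AmAA:0.4,meridionalis:2.5)AA:4.3,",
    "punctata:6.8)AB:8.2,brachyantha:15)Oryza:11,perrieri:26)Root;")
  ape::read.tree(text = nwk)
}

#' Taxon sets defining the evolutionary age groups
#'
#' `asian`: the Asian *Oryza* clade (origins younger than ~0.8 MY);
#' `aa`: all AA-genome species (~0.8-6.8 MY); `ab`: AA plus the BB-genome
#' *O. punctata* (~6.8-26 MY).  Used by [classify_age_group()].
#'
#' @return Named list of character vectors of tip labels.
#' @export
oryza_age_clades <- function() {
  asian <- c("japonica", "nivara", "indica", "rufipogon")
  aa <- c(asian, "glaberrima", "barthii", "glumaepatula", "meridionalis")
  list(asian = asian, aa = aa, ab = c(aa, "punctata"))
}

# label of the branch above `node` (tip label for terminal branches,
# node label for internal ones)
branch_label <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) tree$tip.label[node]
  else tree$node.label[node - ntip]
}

# node number for a branch label (inverse of branch_label)
branch_node <- function(tree, label) {
  ntip <- length(tree$tip.label)
  i <- match(label, tree$tip.label)
  if (!is.na(i)) return(i)
  j <- match(label, tree$node.label)
  if (is.na(j)) stop("unknown branch label: ", label)
  ntip + j
}

#' Tip set descending from a branch
#'
#' @param tree A `phylo` with node labels.
#' @param label Branch label (tip label or internal-node label).
#' @return Character vector of tip labels in the clade below the branch.
#' @export
branch_clade <- function(tree, label) {
  node <- branch_node(tree, label)
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  desc <- phangorn_free_descendants(tree, node)
  tree$tip.label[desc]
}

# tips below an internal node, by edge traversal (no extra dependency)
phangorn_free_descendants <- function(tree, node) {
  ntip <- length(tree$tip.label)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    cur <- stack[[1L]]; stack <- stack[-1L]
    kids <- tree$edge[tree$edge[, 1L] == cur, 2L]
    out <- c(out, kids[kids <= ntip])
    stack <- c(stack, kids[kids > ntip])
  }
  sort(out)
}

# age (MY before present) of every node, from branch lengths
node_ages <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  max(depth) - depth
}

#' All branch labels of a tree (tips first, then internal nodes)
#' @param tree A `phylo` with node labels.
#' @return Character vector.
#' @export
tree_branch_labels <- function(tree) {
  c(tree$tip.label, tree$node.label)
}
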