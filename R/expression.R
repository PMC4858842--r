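#' FPKM from fragment counts
#'
#' count / ((exonic length / 1e3) * (library size / 1e6)).
#'
#' @param count Fragments assigned to the feature.
#' @param length_bp Exonic length (bp), > 0.
#' @param library_size Mapped fragments in the library, > 0.
#' @return FPKM value.
#' @export
fpkm_from_counts <- function(count, length_bp, library_size) {
  if (any(length_bp <= 0) || any(library_size <= 0)) {
    stop("length and library size must be positive")
  }
  count / ((length_bp / 1e3) * (library_size / 1e6))
}

#' Assign an FPKM value to a gene from overlapping FPKM regions
#'
#' An FPKM-bearing interval contributes only when its overlap with the
#' gene covers at least `min_overlap` of the gene length; when several
#' intervals qualify, the maximum FPKM is taken (deterministic,
#' order-independent).  A gene with no qualifying interval gets FPKM 0
#' and is unexpressed.
#'
#' @param gene One-row data.frame `chrom, start, end`.
#' @param fpkm_regions data.frame `chrom, start, end, fpkm`.
#' @param min_overlap Minimum overlapped fraction of the gene length.
#' @return list `fpkm, expressed`.
#' @export
assign_fpkm <- function(gene, fpkm_regions, min_overlap = 0.5) {
  glen <- gene$end - gene$start + 1L
  fpkm <- 0
  if (!is.null(fpkm_regions) && nrow(fpkm_regions) > 0L) {
    sel <- fpkm_regions$chrom == gene$chrom
    if (any(sel)) {
      fr <- fpkm_regions[sel, , drop = FALSE]
      ov <- pmax(0L, pmin(gene$end, fr$end) -
                   pmax(gene$start, fr$start) + 1L)
      ok <- ov / glen >= min_overlap
      if (any(ok)) fpkm <- max(fr$fpkm[ok])
    }
  }
  list(fpkm = fpkm, expressed = fpkm > 0)
}

#' Expression-bias test between a gene set and a background set
#'
#' Two-sided Fisher exact test on the 2x2 table of expressed/unexpressed
#' by set membership in one tissue.
#'
#' @param set_expressed Logical vector: expression flags of the gene set.
#' @param background_expressed Logical vector for the background set.
#' @return list `p, odds_ratio, prop_set, prop_background, table`.
#' @export
tissue_bias_test <- function(set_expressed, background_expressed) {
  if (length(set_expressed) == 0L || length(background_expressed) == 0L) {
    stop("both gene sets must be non-empty")
  }
  tab <- matrix(c(sum(set_expressed), sum(!set_expressed),
                  sum(background_expressed), sum(!background_expressed)),
                nrow = 2L,
                dimnames = list(c("expressed", "unexpressed"),
                                c("set", "background")))
  ft <- stats::fisher.test(tab)
  list(p = ft$p.value, odds_ratio = unname(ft$estimate),
       prop_set = mean(set_expressed),
       prop_background = mean(background_expressed), table = tab)
}

#' Build a cleaned Marey map
#'
#' Drops markers hitting multiple genomic positions, then removes
#' anomalous markers per chromosome by iterative residual filtering
#' against an isotonic (monotone) preliminary fit of genetic on physical
#' position: markers whose residual exceeds 3 robust standard deviations
#' (MAD) are discarded and the fit repeated until stable.  Retained
#' markers are strictly increasing in physical position (duplicate
#' positions collapse to their first marker) and non-decreasing in
#' genetic position.
#'
#' @param markers data.frame `marker, chrom, cM, bp`, optionally
#'   `n_positions` (markers with more than one genomic position are
#'   dropped).
#' @param sd_limit Residual threshold in robust SDs.
#' @param min_markers Minimum surviving markers per chromosome.
#' @return The cleaned data.frame with a `retained` attribute-free
#'   subset, sorted by chromosome and bp.
#' @export
build_marey_map <- function(markers, sd_limit = 3, min_markers = 10L) {
  m <- markers
  if ("n_positions" %in% names(m)) m <- m[m$n_positions == 1L, ]
  dup <- m$marker[duplicated(m$marker)]
  if (length(dup)) m <- m[!m$marker %in% dup, ]
  out <- list()
  for (chrom in unique(m$chrom)) {
    mc <- m[m$chrom == chrom, , drop = FALSE]
    mc <- mc[order(mc$bp), , drop = FALSE]
    mc <- mc[!duplicated(mc$bp), , drop = FALSE]
    repeat {
      if (nrow(mc) < min_markers) {
        stop("fewer than ", min_markers, " markers survive on ", chrom)
      }
      fit <- stats::isoreg(mc$bp, mc$cM)
      res <- mc$cM - fit$yf
      # floor the robust scale above float noise so perfectly monotone
      # maps stop immediately, while a lone gross outlier on an
      # otherwise collinear map (MAD ~ 0) is still caught
      tol <- sqrt(.Machine$double.eps) * max(1, diff(range(mc$cM)))
      s <- max(stats::mad(res), tol)
      # one marker at a time: a gross outlier distorts the isotonic fit
      # (and the residual scale) for its whole neighbourhood, so batch
      # removal would discard genuine markers alongside it
      worst <- which.max(abs(res))
      if (abs(res[worst]) <= sd_limit * s) break
      mc <- mc[-worst, , drop = FALSE]
    }
    # monotone consistency: project onto the final isotonic fit ordering
    fit <- stats::isoreg(mc$bp, mc$cM)
    keep <- mc$cM >= cummax(c(-Inf, utils::head(mc$cM, -1L)))
    mc <- mc[keep, , drop = FALSE]
    if (nrow(mc) < min_markers) {
      stop("fewer than ", min_markers, " markers survive on ", chrom)
    }
    out[[chrom]] <- mc
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# local quadratic fit with tricube weights over the span-nearest markers
local_quad_fit <- function(bp, cM, x0, span = 0.2) {
  n <- length(bp)
  k <- max(5L, ceiling(span * n))
  d <- abs(bp - x0)
  idx <- order(d)[seq_len(min(k, n))]
  h <- max(d[idx])
  w <- if (h == 0) rep(1, length(idx)) else
    pmax(0, (1 - (d[idx] / h)^3))^3
  if (sum(w > 0) < 3L) w <- w + 1e-8
  x <- bp[idx] - x0
  fit <- stats::lm.wfit(cbind(1, x, x^2), cM[idx], w)
  fit$coefficients
}

#' Local recombination rate from a Marey map
#'
#' Fits a local quadratic (LOESS with degree 2, default span 0.2) to
#' genetic vs physical position around the query midpoint and returns the
#' analytic derivative of the fitted curve, clamped at zero, in cM/Mb.
#'
#' @param map Cleaned Marey map for one chromosome
#'   ([build_marey_map()]).
#' @param start,end Query interval (bp); the rate is evaluated at the
#'   midpoint.
#' @param span LOESS span (fraction of markers in the local window).
#' @return list `rate` (cM/Mb), `fitted_cM`, `extrapolated` (TRUE when
#'   the midpoint lies outside the marker range).
#' @export
local_recombination_rate <- function(map, start, end = start,
                                     span = 0.2) {
  stopifnot(nrow(map) >= 10L)
  x0 <- (start + end) / 2
  beta <- local_quad_fit(map$bp, map$cM, x0, span)
  slope <- beta[2L]
  list(rate = max(0, slope * 1e6),
       fitted_cM = unname(beta[1L]),
       extrapolated = x0 < min(map$bp) || x0 > max(map$bp))
}

#' Recombination-rate curve along a chromosome
#'
#' @param map Cleaned Marey map for one chromosome.
#' @param positions Physical positions (bp) at which to evaluate.
#' @param span LOESS span.
#' @return Numeric vector of rates (cM/Mb).
#' @export
recombination_rate_curve <- function(map, positions, span = 0.2) {
  vapply(positions, function(p)
    local_recombination_rate(map, p, span = span)$rate, numeric(1L))
}
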