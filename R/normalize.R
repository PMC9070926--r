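## Groupwise, gene-free normalisation over tiles. One scale factor per
## library is refined by iterated trimming: expression trim at both ends,
## then a variability trim keeping the least-variable fraction by NRMSD,
## then effective library sizes from the unnormalised depths of the kept
## tiles. All libraries are normalised as one group, never pairwise.

#' Normalisation configuration
#'
#' Tunable parameters of [normalize_tiles()]. Defaults implement: removal
#' of the globally least-expressed half of all tiles (these are expected to
#' be the non-transcribed strand), a per-library minimum tile depth of 10
#' (avoids division errors and spurious fluctuation at very low counts),
#' a 10% trim at each expression extreme, retention of the 20%
#' least-variable remaining tiles by NRMSD, and iteration to a 1e-6
#' relative change in every factor.
#'
#' @param low_strand_fraction fraction of all tiles removed up-front as
#'   least-expressed (pooled over both strands).
#' @param min_depth_floor minimum unnormalised tile depth required in
#'   every library.
#' @param expr_trim fraction trimmed at each expression extreme per cycle.
#' @param variability_keep fraction of the post-trim tiles kept, lowest
#'   NRMSD first.
#' @param convergence_tol maximum relative factor change defining
#'   convergence.
#' @param max_iter iteration safety cap.
#' @return a `NormalizationConfig` list.
#' @export
norm_config <- function(low_strand_fraction = 0.50, min_depth_floor = 10,
                        expr_trim = 0.10, variability_keep = 0.20,
                        convergence_tol = 1e-6, max_iter = 100L) {
  fr <- c(low_strand_fraction, expr_trim, variability_keep)
  if (any(fr <= 0) || any(fr >= 1)) stopf("fractions must lie in (0, 1)")
  if (2 * expr_trim >= 1) stopf("expr_trim too large: 2*expr_trim must be < 1")
  if (min_depth_floor < 0) stopf("min_depth_floor must be >= 0")
  structure(list(low_strand_fraction = low_strand_fraction,
                 min_depth_floor = min_depth_floor,
                 expr_trim = expr_trim,
                 variability_keep = variability_keep,
                 convergence_tol = convergence_tol,
                 max_iter = as.integer(max_iter)),
            class = "NormalizationConfig")
}

rescale_gm1 <- function(f) f / geom_mean(f)

#' Preliminary factors from raw aligned-read sizes
#'
#' Factor_i is proportional to 1 / total depth of library i, rescaled so
#' the factors have geometric mean 1 (only ratios matter downstream).
#'
#' @param matrix a [tile_depth_matrix()].
#' @return named numeric vector of positive factors, geometric mean 1.
#' @export
preliminary_factors <- function(matrix) {
  sizes <- library_sizes(matrix)
  if (any(sizes <= 0))
    stopf("library with zero total depth: %s",
          paste(names(sizes)[sizes <= 0], collapse = ", "))
  rescale_gm1(1 / sizes)
}

#' Normalised root-mean-square deviation from the geometric mean
#'
#' With x_i = value_i * factor_i and g their geometric mean, NRMSD =
#' sqrt(mean((x_i - g)^2)) / g. Scale-invariant: multiplying all values by
#' a constant leaves it unchanged.
#'
#' @param values one depth per library (all normalised values must be > 0).
#' @param factors per-library factors, same length/order.
#' @return non-negative scalar.
#' @examples
#' nrmsd(c(1, 2, 4), c(1, 1, 1))  # ~0.6455
#' @export
nrmsd <- function(values, factors) {
  x <- values * factors
  if (any(x <= 0)) stopf("nrmsd requires positive normalised values")
  g <- geom_mean(x)
  sqrt(mean((x - g)^2)) / g
}

## NRMSD for every row of a tiles x libraries matrix (rows all positive
## after scaling). Vectorised version of nrmsd() for the iteration loop.
nrmsd_rows <- function(dep, factors) {
  x <- sweep(dep, 2, factors, `*`)
  g <- exp(rowMeans(log(x)))
  sqrt(rowMeans((x - g)^2)) / g
}

#' Iterative groupwise normalisation
#'
#' Runs, in order: (1) preliminary factors from raw library sizes; (2)
#' removal of the globally least-expressed `low_strand_fraction` of tiles
#' (both strands pooled), ranked by preliminary-factor-normalised mean;
#' (3) removal of any tile below `min_depth_floor` unnormalised depth in
#' any library; (4) iterate — rank by normalised mean and trim `expr_trim`
#' at each end; rank survivors by NRMSD and keep the `variability_keep`
#' least-variable fraction (ties broken by tile coordinate); set each
#' library's effective size to the sum of its unnormalised depths over the
#' kept tiles; recompute factors proportional to 1/effective size with
#' geometric mean 1 — until the largest relative factor change falls below
#' `convergence_tol` or `max_iter` is reached (then a warning flag is set).
#'
#' @param matrix a [tile_depth_matrix()] with at least two libraries.
#' @param config a [norm_config()].
#' @return a `NormalizationResult`: `factors` (geometric mean 1),
#'   `retained_tiles` (data.frame strand/tile of the final kept set),
#'   `iterations`, `converged`, and `trace` (factors per iteration).
#' @export
normalize_tiles <- function(matrix, config = norm_config()) {
  stopifnot(inherits(matrix, "TileDepthMatrix"),
            inherits(config, "NormalizationConfig"))
  if (length(matrix$libraries) < 2L)
    stopf("normalisation needs at least two libraries")
  ax <- matrix$axis
  ## pooled tile table: strand, tile index, depth rows
  dep <- rbind(matrix$depth$forward, matrix$depth$reverse)
  meta <- data.frame(
    strand = rep(c("forward", "reverse"), each = ax$n_tiles),
    tile = rep(seq_len(ax$n_tiles), 2L))

  f <- preliminary_factors(matrix)

  ## stage 2: drop the least-expressed fraction, pooled over strands
  nm <- rowMeans(sweep(dep, 2, f, `*`))
  n_drop <- floor(nrow(dep) * config$low_strand_fraction)
  ord <- order(nm, meta$strand, meta$tile)  # ties resolved by coordinate
  keep <- sort(ord[seq.int(n_drop + 1L, nrow(dep))])
  if (!length(keep)) stopf("low-expression removal emptied the tile set")
  dep <- dep[keep, , drop = FALSE]; meta <- meta[keep, , drop = FALSE]

  ## stage 3: per-library depth floor on unnormalised depths
  ok <- rowSums(dep < config$min_depth_floor) == 0L
  if (!any(ok)) stopf("min-depth floor emptied the tile set")
  dep <- dep[ok, , drop = FALSE]; meta <- meta[ok, , drop = FALSE]

  trace <- list(f)
  converged <- FALSE
  kept_idx <- seq_len(nrow(dep))
  for (it in seq_len(config$max_iter)) {
    nm <- rowMeans(sweep(dep, 2, f, `*`))
    n <- length(nm)
    k <- floor(n * config$expr_trim)
    ord <- order(nm, meta$strand, meta$tile)
    mid <- ord[seq.int(k + 1L, n - k)]
    if (!length(mid)) stopf("expression trim emptied the tile set (iter %d)", it)
    v <- nrmsd_rows(dep[mid, , drop = FALSE], f)
    n_keep <- max(1L, floor(length(mid) * config$variability_keep))
    ordv <- order(v, meta$strand[mid], meta$tile[mid])
    kept_idx <- sort(mid[ordv[seq_len(n_keep)]])
    eff <- colSums(dep[kept_idx, , drop = FALSE])
    if (any(eff <= 0)) stopf("zero effective size after trims (iter %d)", it)
    f_new <- rescale_gm1(1 / eff)
    trace[[it + 1L]] <- f_new
    delta <- max(abs(f_new / f - 1))
    f <- f_new
    if (delta < config$convergence_tol) { converged <- TRUE; break }
  }
  if (!converged)
    warnf("normalisation did not converge in %d iterations", config$max_iter)
  structure(
    list(factors = f,
         retained_tiles = meta[kept_idx, , drop = FALSE],
         iterations = length(trace) - 1L,
         converged = converged,
         trace = do.call(rbind, trace),
         config = config),
    class = "NormalizationResult")
}

#' @export
print.NormalizationResult <- function(x, ...) {
  cat(sprintf("NormalizationResult: %d iterations (%s), %d tiles retained\n",
              x$iterations, if (x$converged) "converged" else "NOT converged",
              nrow(x$retained_tiles)))
  print(round(x$factors, 6))
  invisible(x)
}

#' Merge replicate libraries after normalisation
#'
#' Produces one library per group whose tile values are the mean of the
#' factor-normalised depths of the group members (e.g. merging three
#' replicate vessels per time point into a single per-timepoint profile).
#'
#' @param matrix a [tile_depth_matrix()].
#' @param factors named per-library factors (e.g. from [normalize_tiles()]).
#' @param groups named character vector mapping every library to its group
#'   label; output library order follows the first appearance of each group.
#' @return a [tile_depth_matrix()] with one library per group.
#' @export
merge_replicates <- function(matrix, factors, groups) {
  stopifnot(inherits(matrix, "TileDepthMatrix"))
  missing <- setdiff(matrix$libraries, names(groups))
  if (length(missing))
    stopf("library missing a group tag: %s", paste(missing, collapse = ", "))
  if (!all(matrix$libraries %in% names(factors)))
    stopf("factors must be named for every library")
  glev <- unique(unname(groups[matrix$libraries]))
  merge_one <- function(d) {
    dn <- sweep(d, 2, factors[colnames(d)], `*`)
    out <- vapply(glev, function(g) {
      rowMeans(dn[, groups[colnames(d)] == g, drop = FALSE])
    }, numeric(nrow(d)))
    colnames(out) <- glev
    out
  }
  tile_depth_matrix(matrix$axis, merge_one(matrix$depth$forward),
                    merge_one(matrix$depth$reverse))
}

#' Write normalisation outputs
#'
#' Factors go to a two-column TSV (`library`, `factor`); the run report —
#' config, iterations, convergence, retained-tile count — to JSON.
#'
#' @param result a `NormalizationResult`.
#' @param factors_path,report_path output paths (NULL to skip either).
#' @return invisibly, the report list.
#' @export
write_norm_result <- function(result, factors_path = NULL,
                              report_path = NULL) {
  stopifnot(inherits(result, "NormalizationResult"))
  if (!is.null(factors_path)) {
    utils::write.table(
      data.frame(library = names(result$factors),
                 factor = fmt_num(result$factors)),
      factors_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  rep <- list(config = unclass(result$config),
              iterations = result$iterations,
              converged = result$converged,
              retained_tiles = nrow(result$retained_tiles),
              factors = as.list(result$factors))
  if (!is.null(report_path))
    jsonlite::write_json(rep, report_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  invisible(rep)
}
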