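#' Build a marker catalog from a genome truth or a FASTA tibble
#'
#' @param x A `genome_truth` (uses its embedded markers) or a tibble with
#'   `marker_id` and `sequence`.
#' @return A tibble of class `marker_catalog` with `marker_id`, `sequence`.
#' @export
marker_catalog <- function(x) {
  tbl <- if (inherits(x, "genome_truth")) {
    select(x$markers, "marker_id", "sequence")
  } else {
    stopifnot(all(c("marker_id", "sequence") %in% names(x)))
    select(as_tibble(x), "marker_id", "sequence")
  }
  if (anyDuplicated(tbl$marker_id)) abort("marker ids must be unique")
  class(tbl) <- c("marker_catalog", class(tbl))
  tbl
}

#' Detect marker genes in an assembly
#'
#' A marker is detected only when a single alignment locus covers at least
#' `min_len_frac` of the marker reference at `min_identity` or better
#' (split detections on different contigs do not add up), mirroring the
#' detection threshold of core-gene completeness tools. The best-scoring
#' locus per marker is recorded.
#'
#' @param assembly A `sag_assembly` or contig tibble.
#' @param catalog A `marker_catalog`.
#' @param min_len_frac Minimum fraction of the marker covered by one locus
#'   (default 0.70).
#' @param min_identity Minimum percent identity of the locus (default 95).
#' @param ... Passed to [pairwise_local_hits()].
#' @return A tibble with one row per detected marker: `marker_id`,
#'   `contig_id`, `identity`, `covered_frac`, `sequence` (recovered locus).
#' @export
detect_markers <- function(assembly, catalog, min_len_frac = 0.70,
                           min_identity = 95, ...) {
  if (nrow(catalog) == 0) abort("empty marker catalog")
  contigs <- .contig_tbl(assembly)
  if (nrow(contigs) == 0) {
    return(tibble(marker_id = character(), contig_id = character(),
                  identity = numeric(), covered_frac = numeric(),
                  sequence = character()))
  }
  qt <- tibble(contig_id = catalog$marker_id, sequence = catalog$sequence)
  hits <- pairwise_local_hits(qt, contigs, min_identity = min_identity,
                              min_hit_len = 50, ...)
  if (nrow(hits) == 0) {
    return(tibble(marker_id = character(), contig_id = character(),
                  identity = numeric(), covered_frac = numeric(),
                  sequence = character()))
  }
  mlen <- setNames(nchar(catalog$sequence), catalog$marker_id)
  hits <- mutate(hits,
                 covered_frac = (.data$q_end - .data$q_start) /
                   mlen[.data$query_contig])
  hits <- filter(hits, .data$covered_frac >= min_len_frac)
  if (nrow(hits) == 0) {
    return(tibble(marker_id = character(), contig_id = character(),
                  identity = numeric(), covered_frac = numeric(),
                  sequence = character()))
  }
  best <- hits |>
    group_by(.data$query_contig) |>
    arrange(dplyr::desc(.data$score), .by_group = TRUE) |>
    dplyr::slice(1) |>
    ungroup()
  seqs <- setNames(toupper(contigs$sequence), contigs$contig_id)
  loci <- vapply(seq_len(nrow(best)), function(i) {
    s <- substring(seqs[[best$subject_contig[i]]],
                   best$s_start[i] + 1L, best$s_end[i])
    if (best$strand[i] == "-") {
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    }
    s
  }, "")
  tibble(
    marker_id = best$query_contig,
    contig_id = best$subject_contig,
    identity = best$identity,
    covered_frac = best$covered_frac,
    sequence = loci
  ) |> arrange(.data$marker_id)
}

#' Marker-based genome completeness
#'
#' @param detected Detected marker ids (character vector or the tibble from
#'   [detect_markers()]).
#' @param catalog_size Number of markers in the catalog (default 248).
#' @return A one-row tibble: `n_detected`, `catalog_size`, `percent`
#'   (one decimal). The percentage is first taken at two decimals -- the
#'   precision at which completeness tools print it -- and then rounded
#'   half away from zero to one decimal, so e.g. 169 of 248 reports as
#'   68.2 (68.145 -> 68.15 -> 68.2).
#' @examples
#' completeness(rep("m", 184), 248)$percent  # 74.2
#' @export
completeness <- function(detected, catalog_size = 248) {
  if (catalog_size <= 0) abort("catalog_size must be positive")
  n <- if (is.data.frame(detected)) {
    length(unique(detected$marker_id))
  } else {
    length(detected)
  }
  if (n > catalog_size) abort("more detected markers than catalog entries")
  pct <- .round_half_up(.round_half_up(100 * n / catalog_size, 2), 1)
  tibble(n_detected = as.integer(n),
         catalog_size = as.integer(catalog_size),
         percent = pct)
}

# round half away from zero (base round() is banker's rounding)
.round_half_up <- function(x, digits = 1) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

#' Extrapolate genome size from assembly size and completeness
#'
#' If a fraction `completeness_percent` of the single-copy marker catalog is
#' found in an assembly of `assembly_size` Mbp, the full genome is estimated
#' as `100 * assembly_size / completeness_percent`, reported to one decimal.
#'
#' @param assembly_size Assembly size in Mbp.
#' @param completeness_percent Completeness in percent (> 0).
#' @return Estimated genome size in Mbp, one decimal.
#' @examples
#' estimate_genome_size(48.1, 74.2)  # 64.8
#' @export
estimate_genome_size <- function(assembly_size, completeness_percent) {
  if (completeness_percent <= 0) {
    abort("completeness must be positive to extrapolate a genome size")
  }
  .round_half_up(100 * assembly_size / completeness_percent, 1)
}

#' Build a saturation-curve tibble
#'
#' @param x Effort values (read fraction, Gbp, or number of SAGs).
#' @param y Recovery values, one per (x, replicate) point.
#' @param replicate Replicate index per point.
#' @return A tibble of class `saturation_curve` with columns `x`,
#'   `replicate`, `y`, sorted by `x`.
#' @export
saturation_curve <- function(x, y, replicate = 1L) {
  out <- tibble(x = x, replicate = replicate, y = y) |> arrange(.data$x)
  if (is.unsorted(unique(out$x))) abort("x must be sortable")
  class(out) <- c("saturation_curve", class(out))
  out
}

#' Fit a Michaelis-Menten saturation model
#'
#' Fits `y = Vmax * x / (Km + x)` by nonlinear least squares over all
#' points (replicates pooled, not averaged). Starting values come from the
#' Hanes-Woolf linearization `x/y = x/Vmax + Km/Vmax`; the nonlinear fit
#' uses Levenberg-Marquardt. `Vmax` is the extrapolated asymptote (e.g.
#' total genome size when `y` is cumulative assembly size).
#'
#' @param curve A `saturation_curve` or tibble with `x`, `y`.
#' @return An object of class `mm_fit`: list with `vmax`, `km`,
#'   `residual_norm`, `diverged` (TRUE when the data do not saturate or the
#'   optimizer failed, in which case the Hanes-Woolf estimates are
#'   returned), and `fitted` function.
#' @export
fit_michaelis_menten <- function(curve) {
  pts <- filter(as_tibble(curve), is.finite(.data$x), is.finite(.data$y))
  if (length(unique(pts$x)) < 3) abort("need >= 3 distinct effort values")
  pos <- filter(pts, .data$y > 0, .data$x > 0)
  if (nrow(pos) >= 2) {
    hw <- lm(I(x / y) ~ x, data = pos)
    vmax0 <- 1 / coef(hw)[["x"]]
    km0 <- coef(hw)[["(Intercept)"]] * vmax0
  } else {
    vmax0 <- km0 <- NA_real_
  }
  if (!is.finite(vmax0) || vmax0 <= 0) vmax0 <- 1.05 * max(pts$y)
  if (!is.finite(km0) || km0 <= 0) km0 <- median(pts$x)
  diverged <- FALSE
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ vmax * x / (km + x), data = pts,
      start = list(vmax = vmax0, km = km0),
      lower = c(vmax = 1e-9, km = 1e-9),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    diverged <- TRUE
    vmax <- vmax0
    km <- km0
    resid <- sqrt(sum((pts$y - vmax * pts$x / (km + pts$x))^2))
  } else {
    cf <- coef(fit)
    vmax <- cf[["vmax"]]
    km <- cf[["km"]]
    resid <- sqrt(sum(stats::residuals(fit)^2))
  }
  # non-saturating data: flag when recovery keeps rising ~linearly
  if (!diverged && km > 100 * max(pts$x)) diverged <- TRUE
  if (sd(pts$y) > 0 && stats::cor(pts$x, pts$y) < 0) {
    warn("saturation curve decreases with effort; fit flagged as diverged")
    diverged <- TRUE
  }
  structure(
    list(vmax = vmax, km = km, residual_norm = resid, diverged = diverged,
         n_points = nrow(pts),
         fitted = function(x) vmax * x / (km + x)),
    class = "mm_fit"
  )
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("<mm_fit> Vmax = %.4g, Km = %.4g, residual norm %.4g%s\n",
              x$vmax, x$km, x$residual_norm,
              if (x$diverged) " [diverged]" else ""))
  invisible(x)
}

#' Cumulative co-assembly curve over increasing numbers of cells
#'
#' For each of `n_orderings` random permutations of the cells and each
#' prefix size k, computes the chosen metric of the union of the first k
#' assemblies, then fits a Michaelis-Menten curve to all (k, metric) points;
#' `Vmax` is the extrapolated total genome size (or asymptotic
#' completeness). When simulator truth intervals are present the union is
#' exact interval arithmetic; otherwise a greedy non-redundant merge based
#' on >= 95%-identity hits is used.
#'
#' @param sags List of `sag_assembly` objects (>= 3).
#' @param n_orderings Number of random cell orderings (default 20).
#' @param seed Integer seed.
#' @param metric `"assembly_size"` (union bp) or `"completeness"` (percent
#'   of `catalog` markers with a single >= `min_len_frac` locus inside the
#'   union).
#' @param catalog Required for `metric = "completeness"`: a
#'   `marker_catalog` built from the same `genome_truth` (truth mode) or a
#'   reference catalog (merge mode).
#' @param genome The `genome_truth`, required for truth-mode completeness.
#' @param min_len_frac Single-locus coverage threshold (default 0.70).
#' @return A list: `curve` (`saturation_curve` of per-ordering prefix
#'   values), `fit` (`mm_fit`), `mode` ("truth" or "merge").
#' @export
cumulative_coassembly_curve <- function(sags, n_orderings = 20, seed = 1,
                                        metric = c("assembly_size",
                                                   "completeness"),
                                        catalog = NULL, genome = NULL,
                                        min_len_frac = 0.70) {
  metric <- match.arg(metric)
  if (length(sags) < 3) abort("need at least 3 cells")
  truth_ok <- all(vapply(sags, function(s) {
    !is.null(s$truth) && nrow(s$truth$intervals) > 0
  }, TRUE))
  if (metric == "completeness" && is.null(catalog)) {
    abort("completeness metric needs a marker catalog")
  }
  n <- length(sags)
  vals <- withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n_orderings), function(o) {
      ord <- sample.int(n)
      if (truth_ok) {
        union_iv <- tibble(start = integer(), end = integer())
        purrr::map_dfr(seq_len(n), function(k) {
          union_iv <<- .iv_reduce(bind_rows(union_iv,
                                            sags[[ord[k]]]$truth$intervals))
          y <- if (metric == "assembly_size") {
            .iv_total(union_iv)
          } else {
            .truth_completeness(union_iv, genome, catalog, min_len_frac)
          }
          tibble(x = k, replicate = o, y = y)
        })
      } else {
        merged <- NULL
        purrr::map_dfr(seq_len(n), function(k) {
          merged <<- .merge_nonredundant(merged, sags[[ord[k]]])
          y <- if (metric == "assembly_size") {
            sum(nchar(merged$sequence))
          } else {
            det <- detect_markers(merged, catalog,
                                  min_len_frac = min_len_frac)
            completeness(det, nrow(catalog))$percent
          }
          tibble(x = k, replicate = o, y = y)
        })
      }
    })
  })
  curve <- saturation_curve(vals$x, vals$y, vals$replicate)
  list(curve = curve, fit = fit_michaelis_menten(curve),
       mode = if (truth_ok) "truth" else "merge")
}

# completeness over a truth-interval union: a marker counts iff one union
# run covers >= min_len_frac of it
.truth_completeness <- function(union_iv, genome, catalog, min_len_frac) {
  stopifnot(inherits(genome, "genome_truth"))
  mk <- genome$markers
  mk <- mk[mk$marker_id %in% catalog$marker_id, ]
  if (nrow(mk) == 0) return(0)
  ov <- IRanges::findOverlaps(.iv_to_iranges(mk), .iv_to_iranges(union_iv))
  det <- logical(nrow(mk))
  if (length(ov)) {
    qh <- S4Vectors::queryHits(ov)
    sh <- S4Vectors::subjectHits(ov)
    inter <- pmin(mk$end[qh], union_iv$end[sh]) -
      pmax(mk$start[qh], union_iv$start[sh])
    frac <- inter / (mk$end[qh] - mk$start[qh])
    det[unique(qh[frac >= min_len_frac])] <- TRUE
  }
  .round_half_up(100 * sum(det) / nrow(catalog), 1)
}

# greedy non-redundant merge: keep current contigs, append the parts of the
# incoming assembly not covered by >= 95%-identity hits to the current set
.merge_nonredundant <- function(current, sag) {
  inc <- .contig_tbl(sag)
  if (is.null(current)) {
    return(select(inc, "contig_id", "sequence"))
  }
  hits <- pairwise_local_hits(inc, current, min_identity = 95)
  keep_parts <- purrr::map_dfr(seq_len(nrow(inc)), function(i) {
    len <- nchar(inc$sequence[i])
    h <- hits[hits$query_contig == inc$contig_id[i], ]
    cov <- if (nrow(h)) {
      IRanges::reduce(IRanges::IRanges(h$q_start + 1L, h$q_end))
    } else IRanges::IRanges()
    gaps <- IRanges::setdiff(IRanges::IRanges(1L, len), cov)
    gaps <- gaps[IRanges::width(gaps) >= 100]  # ignore slivers
    if (length(gaps) == 0) return(NULL)
    tibble(
      contig_id = sprintf("%s_part%d", inc$contig_id[i],
                          seq_along(gaps)),
      sequence = substring(inc$sequence[i], BiocGenerics::start(gaps),
                           BiocGenerics::end(gaps))
    )
  })
  bind_rows(select(current, "contig_id", "sequence"), keep_parts)
}
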