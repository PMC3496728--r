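#' Validate a table of raw Ct records
#'
#' Checks the long-format Ct table used throughout the pipeline: one row per
#' technical replicate with columns `gene`, `colony`, `zt`, `replicate`, `ct`.
#'
#' @param data A data frame of Ct records.
#' @return The input as a tibble, invisibly validated.
#' @keywords internal
validate_ct_records <- function(data) {
  required <- c("gene", "colony", "zt", "replicate", "ct")
  missing <- setdiff(required, names(data))
  if (length(missing) > 0) {
    abort(paste0("Ct table is missing column(s): ", paste(missing, collapse = ", ")))
  }
  data <- as_tibble(data)
  if (nrow(data) == 0) abort("Ct table is empty")
  if (!all(is.finite(data$ct)) || any(data$ct <= 0)) {
    abort("all Ct values must be finite and > 0")
  }
  if (!all(is.finite(data$zt)) || any(data$zt < 0)) {
    abort("all zt values must be finite and >= 0")
  }
  dup <- data |>
    count(.data$gene, .data$colony, .data$zt, .data$replicate) |>
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    key <- dup[1, ]
    abort(sprintf(
      "duplicate Ct record for (gene=%s, colony=%s, zt=%s, replicate=%s)",
      key$gene, key$colony, key$zt, key$replicate
    ))
  }
  data
}

#' Per-cell delta-Ct against a reference gene
#'
#' Averages Ct across technical replicates within each (colony, zt) cell and
#' subtracts the replicate-mean Ct of the reference (housekeeping) gene
#' measured in the same cell: dCt = mean(Ct_target) - mean(Ct_reference).
#' Because one PCR cycle corresponds to one template doubling, a unit drop in
#' dCt is a two-fold rise in relative expression.
#'
#' Outlying replicates are not dropped; all replicates enter the cell mean.
#'
#' @param data Long-format Ct table (`gene`, `colony`, `zt`, `replicate`,
#'   `ct`) containing both target genes and the reference gene.
#' @param reference Identifier of the reference gene (e.g. `"EF1a"`). Must be
#'   present in `data` at every (colony, zt) cell covered by the targets.
#' @return A tibble with columns `gene`, `colony`, `zt`, `delta_ct`, one row
#'   per target-gene cell. The reference gene itself is excluded.
#' @examples
#' ct <- tibble::tibble(
#'   gene = rep(c("per", "EF1a"), each = 3),
#'   colony = "A", zt = 2, replicate = rep(1:3, 2),
#'   ct = c(24.1, 24.3, 24.2, 18.0, 18.1, 17.9)
#' )
#' compute_delta_ct(ct, reference = "EF1a")
#' @export
compute_delta_ct <- function(data, reference) {
  data <- validate_ct_records(data)
  if (!reference %in% data$gene) {
    abort(sprintf("reference gene '%s' not found in Ct table", reference))
  }
  cell_means <- data |>
    group_by(.data$gene, .data$colony, .data$zt) |>
    summarise(mean_ct = mean(.data$ct), .groups = "drop")
  ref <- cell_means |>
    filter(.data$gene == reference) |>
    select(colony = "colony", zt = "zt", ref_ct = "mean_ct")
  out <- cell_means |>
    filter(.data$gene != reference) |>
    left_join(ref, by = c("colony", "zt"))
  bad <- filter(out, is.na(.data$ref_ct))
  if (nrow(bad) > 0) {
    abort(sprintf(
      "no reference ('%s') measurement for cell (gene=%s, colony=%s, zt=%s)",
      reference, bad$gene[1], bad$colony[1], bad$zt[1]
    ))
  }
  out |>
    mutate(delta_ct = .data$mean_ct - .data$ref_ct) |>
    select("gene", "colony", "zt", "delta_ct") |>
    arrange(.data$gene, .data$colony, .data$zt)
}

#' Relative quantities (fold changes) from delta-Ct values
#'
#' Subtracts a per-(gene, colony) calibrator from each delta-Ct to obtain
#' delta-delta-Ct and converts to fold change as 2^(-ddCt). With the default
#' `"mean_over_time"` calibrator each series is expressed relative to its own
#' across-time mean, so the geometric mean of the folds is exactly 1 per
#' series; `"first_timepoint"` instead uses the earliest sampled zt.
#'
#' @param data Tibble with columns `gene`, `colony`, `zt`, `delta_ct`, as
#'   returned by [compute_delta_ct()].
#' @param calibrator Calibrator rule, `"mean_over_time"` (default) or
#'   `"first_timepoint"`.
#' @return Input tibble with added columns `delta_delta_ct` and `fold`.
#' @export
relative_quantity <- function(data, calibrator = c("mean_over_time", "first_timepoint")) {
  calibrator <- match.arg(calibrator)
  if (nrow(data) == 0) abort("empty delta-Ct table")
  data |>
    group_by(.data$gene, .data$colony) |>
    arrange(.data$zt, .by_group = TRUE) |>
    mutate(
      delta_delta_ct = .data$delta_ct - switch(calibrator,
        mean_over_time = mean(.data$delta_ct),
        first_timepoint = .data$delta_ct[1]
      ),
      fold = 2^(-.data$delta_delta_ct)
    ) |>
    ungroup()
}

#' Standardize a numeric sequence to z-scores
#'
#' Centers and scales with the sample standard deviation (n - 1 denominator),
#' giving the "number of standard deviations above and below the mean" scale
#' used for plotting and rhythm fitting. A constant input has no scale; it is
#' returned as all zeros with a warning.
#'
#' @param x Numeric vector, length >= 2.
#' @return Numeric vector of z-scores, same length as `x`.
#' @examples
#' standardize(c(1, 2, 3)) # -1, 0, 1
#' @export
standardize <- function(x) {
  if (length(x) < 2) abort("standardize() needs at least 2 values")
  if (!all(is.finite(x))) abort("standardize() requires finite values")
  s <- sd(x)
  if (s == 0) {
    warn("constant input to standardize(); returning zeros")
    return(rep(0, length(x)))
  }
  (x - mean(x)) / s
}

#' Ct table to z-scored relative expression series
#'
#' The full per-gene quantification chain: delta-Ct against the reference,
#' calibration to delta-delta-Ct and fold change, then z-scoring of the log2
#' relative expression (-ddCt) within each (gene, colony) series. Z-scoring
#' on the log scale keeps a Ct-scale cosine exactly sinusoidal and removes
#' colony baseline differences before cross-colony averaging.
#'
#' @inheritParams compute_delta_ct
#' @inheritParams relative_quantity
#' @return A tibble with columns `gene`, `colony`, `zt`, `delta_ct`,
#'   `delta_delta_ct`, `fold`, `zscore`, sorted by gene, colony, zt.
#' @export
quantify_expression <- function(data, reference,
                                calibrator = c("mean_over_time", "first_timepoint")) {
  calibrator <- match.arg(calibrator)
  compute_delta_ct(data, reference) |>
    relative_quantity(calibrator) |>
    group_by(.data$gene, .data$colony) |>
    mutate(zscore = standardize(-.data$delta_delta_ct)) |>
    ungroup()
}

#' Average z-scored expression across colonies
#'
#' Per-gene, per-timepoint mean and standard error of the colony z-scores.
#' The standard error is the sample standard deviation across colonies
#' divided by sqrt(number of colonies); with a single colony it is reported
#' as 0 with a warning.
#'
#' @param data Tibble with columns `gene`, `colony`, `zt`, `zscore`, as
#'   returned by [quantify_expression()]. All colonies of a gene must share
#'   the same zt grid.
#' @return A tibble with columns `gene`, `zt`, `mean_z`, `se_z`,
#'   `n_colonies`.
#' @export
aggregate_colonies <- function(data) {
  if (nrow(data) == 0) abort("empty expression table")
  grids <- data |>
    group_by(.data$gene, .data$colony) |>
    summarise(grid = paste(sort(.data$zt), collapse = ","), .groups = "drop_last") |>
    summarise(n_grids = n_distinct(.data$grid), .groups = "drop")
  if (any(grids$n_grids > 1)) {
    abort(sprintf("colonies of gene '%s' have mismatched zt grids",
                  grids$gene[grids$n_grids > 1][1]))
  }
  if (n_distinct(data$colony) == 1) {
    warn("single colony: se_z reported as 0")
  }
  data |>
    group_by(.data$gene, .data$zt) |>
    summarise(
      mean_z = mean(.data$zscore),
      se_z = if (n() > 1) sd(.data$zscore) / sqrt(n()) else 0,
      n_colonies = n(),
      .groups = "drop"
    ) |>
    arrange(.data$gene, .data$zt)
}
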