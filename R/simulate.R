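#' Specify a simulated gene
#'
#' One row of ground truth for the qPCR simulator: the gene's baseline Ct,
#' the amplitude of its 24-h oscillation on the Ct scale (one Ct unit is one
#' expression doubling), and its acrophase (hour of peak expression, i.e.
#' lowest Ct). The reference gene must be flat.
#'
#' @param gene Gene identifier.
#' @param baseline_ct Mean Ct level (typically 15-30).
#' @param amplitude_ct Oscillation amplitude in Ct units (>= 0).
#' @param acrophase Peak-expression hour in \[0, 24).
#' @param is_reference Whether this gene is the flat housekeeping reference.
#' @return One-row tibble.
#' @export
gene_spec <- function(gene, baseline_ct, amplitude_ct = 0, acrophase = 0,
                      is_reference = FALSE) {
  if (amplitude_ct < 0) abort("amplitude_ct must be >= 0")
  if (is_reference && amplitude_ct != 0) {
    abort("the reference gene must have amplitude_ct = 0")
  }
  if (acrophase < 0 || acrophase >= 24) abort("acrophase must lie in [0, 24)")
  tibble(
    gene = gene, baseline_ct = baseline_ct, amplitude_ct = amplitude_ct,
    acrophase = acrophase, is_reference = is_reference
  )
}

#' Default simulated clock-gene panel
#'
#' A nine-gene panel mirroring a social-insect brain study: a flat EF1a
#' reference, four genuine oscillators (per and cry-m peaking in the night
#' at ZT 18, cwo and cyc anti-phase at ZT 6, Ct-scale amplitudes 1-1.2) and
#' four arrhythmic genes (clk, pdp1, tim2, vri).
#'
#' @return Tibble of [gene_spec()] rows.
#' @export
default_gene_panel <- function() {
  bind_rows(
    gene_spec("EF1a", 18, 0, 0, is_reference = TRUE),
    gene_spec("per", 24, 1.2, 18),
    gene_spec("cry-m", 25, 1.0, 18),
    gene_spec("cwo", 24, 1.0, 6),
    gene_spec("cyc", 25, 1.1, 6),
    gene_spec("clk", 24, 0, 0),
    gene_spec("pdp1", 26, 0, 0),
    gene_spec("tim2", 24, 0, 0),
    gene_spec("vri", 25, 0, 0)
  )
}

#' Simulation configuration for a qPCR time course
#'
#' Encodes the study geometry: number of colonies, the Zeitgeber-time
#' sampling grid, technical replicates per sample, and the two Gaussian
#' noise sources on the Ct scale (a per-(gene, colony) baseline offset and
#' independent per-reaction noise). Defaults reproduce a three-colony,
#' seven-timepoint (every 4 h across one 12:12 LD day), triplicate design
#' with 0.5 Ct colony offsets and 0.25 Ct replicate noise.
#'
#' @param genes Tibble of [gene_spec()] rows.
#' @param n_colonies Number of colonies.
#' @param zts Sampling times in hours since lights-on (may exceed 24).
#' @param n_replicates Technical replicates per (gene, colony, zt).
#' @param colony_offset_sd SD of per-(gene, colony) Ct offsets.
#' @param replicate_noise_sd SD of per-reaction Ct noise.
#' @param seed Integer seed; the dataset is fully determined by it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(genes = default_gene_panel(), n_colonies = 3,
                       zts = seq(2, 26, by = 4), n_replicates = 3,
                       colony_offset_sd = 0.5, replicate_noise_sd = 0.25,
                       seed = 1) {
  if (n_colonies < 1 || n_replicates < 1) {
    abort("n_colonies and n_replicates must be >= 1")
  }
  if (colony_offset_sd < 0 || replicate_noise_sd < 0) {
    abort("noise standard deviations must be >= 0")
  }
  if (nrow(genes) == 0) abort("at least one gene is required")
  if (any(genes$is_reference & genes$amplitude_ct != 0)) {
    abort("the reference gene must have amplitude_ct = 0")
  }
  structure(
    list(
      genes = genes, n_colonies = n_colonies, zts = sort(unique(zts)),
      n_replicates = n_replicates, colony_offset_sd = colony_offset_sd,
      replicate_noise_sd = replicate_noise_sd, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Simulate a qPCR Ct dataset with known rhythmic ground truth
#'
#' Generates Ct(gene, colony, zt, replicate) = baseline + colony offset
#' - amplitude * cos(2 pi (zt - acrophase) / 24) + noise. The cosine enters
#' with a minus sign because a lower Ct means more template: expression
#' 2^(-ddCt) then oscillates with the specified acrophase. Colony offsets
#' are drawn per (gene, colony) from Normal(0, colony_offset_sd) and
#' reaction noise from Normal(0, replicate_noise_sd); everything is
#' determined by the config seed.
#'
#' @param config A [sim_config()].
#' @return Long-format Ct tibble (`gene`, `colony`, `zt`, `replicate`,
#'   `ct`) ready for [quantify_expression()].
#' @examples
#' ct <- simulate_qpcr(sim_config(seed = 42))
#' head(ct)
#' @export
simulate_qpcr <- function(config) {
  if (!inherits(config, "sim_config")) {
    abort("config must be created with sim_config()")
  }
  colonies <- sprintf("colony%02d", seq_len(config$n_colonies))
  grid <- tidyr::expand_grid(
    gene = config$genes$gene,
    colony = colonies,
    zt = config$zts,
    replicate = seq_len(config$n_replicates)
  ) |>
    left_join(config$genes, by = "gene")
  withr::with_seed(config$seed, {
    offsets <- tidyr::expand_grid(gene = config$genes$gene, colony = colonies) |>
      mutate(offset = rnorm(n(), 0, config$colony_offset_sd))
    grid |>
      left_join(offsets, by = c("gene", "colony")) |>
      mutate(
        ct = .data$baseline_ct + .data$offset -
          .data$amplitude_ct * cos(2 * pi * (.data$zt - .data$acrophase) / 24) +
          rnorm(n(), 0, config$replicate_noise_sd)
      ) |>
      select("gene", "colony", "zt", "replicate", "ct")
  })
}

#' Simulate a protein pair with a known number of substitutions
#'
#' Draws a random amino-acid sequence and copies it with exactly
#' `n_mutations` positions substituted for a different residue (no indels),
#' so that a gap-free global alignment has identity
#' 100 (length - n_mutations) / length. Deterministic given `seed`.
#'
#' @param length Sequence length.
#' @param n_mutations Number of substituted positions, in \[0, length\].
#' @param seed Integer seed.
#' @return Tibble with columns `id` (`"ancestral"`, `"derived"`) and
#'   `residues`.
#' @export
simulate_domain_pair <- function(length, n_mutations, seed = 1) {
  if (length < 1) abort("length must be >= 1")
  if (n_mutations < 0 || n_mutations > length) {
    abort("n_mutations must lie in [0, length]")
  }
  withr::with_seed(seed, {
    res <- sample(AA_ALPHABET20, length, replace = TRUE)
    mut <- res
    if (n_mutations > 0) {
      pos <- sample.int(length, n_mutations)
      mut[pos] <- vapply(res[pos], function(r) {
        sample(setdiff(AA_ALPHABET20, r), 1)
      }, character(1))
    }
    tibble(
      id = c("ancestral", "derived"),
      residues = c(paste(res, collapse = ""), paste(mut, collapse = ""))
    )
  })
}
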