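#' Design of a simulated titration
#'
#' Describes how a synthetic fluorescence titration is laid out. The
#' defaults reproduce the design of the real experiments this package
#' analyses: a zero-ligand baseline followed by 24 log-spaced additions
#' spanning 2 uM to 5 mM of cap analogue, 0.1 uM nominal protein,
#' homoscedastic Gaussian noise scaled to the baseline fluorescence, and
#' an optional linear apo-protein signal drift (unstable protein
#' preparations lose 10-25% of their signal over a run, which is exactly
#' the artefact that motivates stabilizing buffers before titrating).
#'
#' @param ligand_schedule total-ligand concentrations in the cuvette, uM;
#'   non-decreasing and starting at 0. Default: 0 plus 24 log-spaced
#'   points spanning 0.02-5000 uM. The upper end is the 5 mM top of the
#'   titrant stock range; the sub-micromolar lower end is what small
#'   additions of the dilute (2 uM) stock deliver in the cuvette, and is
#'   essential: with 0.1 uM protein and dissociation constants down to a
#'   few nM, the binding transition lives below 1 uM, and a schedule
#'   that only sampled micromolar ligand would leave the association
#'   constant unidentifiable (every point past saturation).
#' @param protein_nominal nominal total protein, uM (0.1 or 0.2 in the
#'   standard designs).
#' @param addition_volumes optional per-point cumulative sample volume,
#'   uL.
#' @param noise_sd_frac Gaussian noise SD as a fraction of `f0`.
#' @param drift_total_frac total fraction of `f0` lost linearly (in point
#'   index) over the run at zero ligand; 0.10 or 0.25 emulate the
#'   documented instability of untreated eIF4E1b preparations.
#' @param seed integer seed; identical seeds give bit-identical curves.
#' @return list of class `simulation_design`.
#' @export
simulation_design <- function(ligand_schedule = NULL,
                              protein_nominal = 0.1,
                              addition_volumes = NULL,
                              noise_sd_frac = 0.01,
                              drift_total_frac = 0,
                              seed = 1L) {
  if (is.null(ligand_schedule))
    ligand_schedule <- c(0, 10^seq(log10(0.02), log10(5000), length.out = 24))
  if (ligand_schedule[1] != 0 || any(diff(ligand_schedule) < 0))
    stop("ligand_schedule must be non-decreasing and start at 0")
  if (noise_sd_frac < 0) stop("noise_sd_frac must be >= 0")
  if (drift_total_frac < 0 || drift_total_frac >= 1)
    stop("drift_total_frac must lie in [0, 1)")
  if (!is.null(addition_volumes) &&
      length(addition_volumes) != length(ligand_schedule))
    stop("addition_volumes must match the ligand schedule length")
  structure(list(ligand_schedule = ligand_schedule,
                 protein_nominal = protein_nominal,
                 addition_volumes = addition_volumes,
                 noise_sd_frac = noise_sd_frac,
                 drift_total_frac = drift_total_frac,
                 seed = as.integer(seed)),
            class = "simulation_design")
}

#' Simulate one fluorescence titration with known ground truth
#'
#' Evaluates the forward model at the design's ligand schedule, applies a
#' linear-in-index apo-signal drift factor `(1 - drift * i/(n-1))`, and
#' adds Gaussian noise with SD `noise_sd_frac * f0`. With zero noise and
#' zero drift every point equals [model_fluorescence()] exactly.
#'
#' @param truth a [binding_parameters()] object (the generating values).
#' @param design a [simulation_design()].
#' @param protein_id,ligand,buffer_tag identity metadata for the curve.
#' @return a [titration_curve()]; fluorescence may be clipped at 0 if
#'   noise drives a point negative (essentially impossible at realistic
#'   noise levels).
#' @export
simulate_titration <- function(truth, design = simulation_design(),
                               protein_id = "simulated",
                               ligand = "m7GTP",
                               buffer_tag = "standard") {
  stopifnot(inherits(truth, "binding_parameters"),
            inherits(design, "simulation_design"))
  L <- design$ligand_schedule
  n <- length(L)
  f_model <- model_fluorescence(truth, L)
  drift <- if (n > 1)
    1 - design$drift_total_frac * (seq_len(n) - 1) / (n - 1)
  else 1
  set.seed(design$seed)
  noise <- if (design$noise_sd_frac > 0)
    rnorm(n, 0, design$noise_sd_frac * truth$f0)
  else numeric(n)
  points <- data.frame(ligand_total = L,
                       fluorescence_raw = pmax(f_model * drift + noise, 0))
  if (!is.null(design$addition_volumes))
    points$volume <- design$addition_volumes
  titration_curve(protein_id, ligand, points, buffer_tag = buffer_tag)
}

#' Simulate a replicate titration study
#'
#' Generates `replicates_per_cell` curves for every (protein, ligand,
#' true kas) cell, each with its own deterministic seed derived from the
#' design seed, plus a manifest of the generating parameters — the
#' synthetic stand-in for a full affinity study whose raw data can then
#' be pushed through fit, pooling and thermodynamic stages.
#'
#' @param cells data frame with columns `protein_id`, `ligand`, `kas`
#'   (true association constant, uM^-1) and optionally `buffer_tag`.
#' @param replicates_per_cell number of independent titrations per cell
#'   (2-6 in a typical study; any >= 1 accepted).
#' @param design a [simulation_design()]; per-curve seeds are derived
#'   from `design$seed`.
#' @param f0,delta_f,f_lig shared non-affinity truth parameters.
#' @return list with `curves` (list of [titration_curve()]), `truth`
#'   (list of matching [binding_parameters()]) and `manifest` (one row
#'   per cell).
#' @export
simulate_replicate_study <- function(cells, replicates_per_cell = 3,
                                     design = simulation_design(),
                                     f0 = 1000, delta_f = 5000,
                                     f_lig = 1.5) {
  cells <- as.data.frame(cells)
  if (nrow(cells) == 0L) stop("cells must contain at least one row")
  if (!all(c("protein_id", "ligand", "kas") %in% names(cells)))
    stop("cells must have columns protein_id, ligand, kas")
  if (is.null(cells$buffer_tag)) cells$buffer_tag <- "standard"
  if (replicates_per_cell < 1) stop("replicates_per_cell must be >= 1")

  curves <- list(); truth <- list()
  idx <- 0L
  for (i in seq_len(nrow(cells))) {
    pars <- binding_parameters(cells$kas[i], design$protein_nominal,
                               f0, delta_f, f_lig)
    for (r in seq_len(replicates_per_cell)) {
      idx <- idx + 1L
      d <- design
      d$seed <- (design$seed %% 1000000L) * 1000L + idx
      curves[[idx]] <- simulate_titration(
        pars, d, protein_id = cells$protein_id[i],
        ligand = cells$ligand[i], buffer_tag = cells$buffer_tag[i])
      truth[[idx]] <- pars
    }
  }
  manifest <- cells
  manifest$p0_act <- design$protein_nominal
  manifest$f0 <- f0; manifest$delta_f <- delta_f; manifest$f_lig <- f_lig
  manifest$replicates <- replicates_per_cell
  list(curves = curves, truth = truth, manifest = manifest)
}

#' Simulate a family-labelled alignment with planted discriminating columns
#'
#' Builds a toy paralog alignment: two families (A and B) share a random
#' background consensus with independent per-residue substitution noise,
#' while a chosen number of planted columns are fully conserved within
#' each family with different residues between families — the signature
#' that [find_discriminating_positions()] is designed to detect.
#'
#' @param n_a,n_b sequences per family (>= 2 each for downstream
#'   analysis).
#' @param n_col alignment columns.
#' @param n_planted number of planted discriminating columns.
#' @param sub_rate per-residue probability of a random substitution in
#'   background columns.
#' @param gap_rate per-residue probability of a gap in background
#'   columns.
#' @param seed integer seed.
#' @return list with `aln` (a [labelled_alignment()]) and
#'   `planted_columns` (integer column indices).
#' @export
simulate_labelled_alignment <- function(n_a = 8, n_b = 8, n_col = 120,
                                        n_planted = 15, sub_rate = 0.05,
                                        gap_rate = 0, seed = 1L) {
  stopifnot(n_a >= 2, n_b >= 2, n_planted <= n_col)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  set.seed(seed)
  consensus <- sample(aa, n_col, replace = TRUE)
  planted <- sort(sample(n_col, n_planted))
  n <- n_a + n_b
  mat <- matrix(rep(consensus, each = n), nrow = n)
  for (j in setdiff(seq_len(n_col), planted)) {
    hit <- runif(n) < sub_rate
    if (any(hit)) mat[hit, j] <- sample(aa, sum(hit), replace = TRUE)
    if (gap_rate > 0) {
      gap <- runif(n) < gap_rate
      if (any(gap)) mat[gap, j] <- "-"
    }
  }
  for (j in planted) {
    pair <- sample(aa, 2)
    mat[seq_len(n_a), j] <- pair[1]
    mat[n_a + seq_len(n_b), j] <- pair[2]
  }
  ids <- c(paste0("famA_", seq_len(n_a)), paste0("famB_", seq_len(n_b)))
  seqs <- setNames(apply(mat, 1, paste, collapse = ""), ids)
  fams <- setNames(rep(c("A", "B"), c(n_a, n_b)), ids)
  list(aln = labelled_alignment(seqs, fams, reference_id = ids[1]),
       planted_columns = planted)
}
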