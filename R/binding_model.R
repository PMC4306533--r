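#' Binding parameters of the fluorescence titration model
#'
#' Parameters of the single-site equilibrium model observed by intrinsic
#' protein fluorescence quenching. The observable is
#' `F(L0) = f0 - delta_f * [PL] + f_lig * (L0 - [PL])`, where `[PL]` is the
#' complex concentration from the ligand-depletion isotherm. `f0` is a
#' single baseline absorbing the emission of both active and inactive
#' apo-protein (the inactive fraction is not separately identifiable from
#' titration data); `delta_f` is the quench amplitude per uM of complex
#' (`f_Pact - f_PL`); `f_lig` is the emission efficiency of free ligand,
#' which dominates the signal at millimolar cap concentrations.
#'
#' @param kas association constant, uM^-1; must be > 0.
#' @param p0_act total active protein concentration, uM; >= 0.
#' @param f0 baseline fluorescence at zero ligand, arbitrary units.
#' @param delta_f quench coefficient, fluorescence per uM of complex; >= 0
#'   for quenching systems.
#' @param f_lig free-ligand fluorescence efficiency, per uM; >= 0.
#' @return an object of class `binding_parameters`.
#' @export
binding_parameters <- function(kas, p0_act, f0, delta_f, f_lig) {
  kas <- as.numeric(kas); p0_act <- as.numeric(p0_act)
  f0 <- as.numeric(f0); delta_f <- as.numeric(delta_f)
  f_lig <- as.numeric(f_lig)
  if (!is.finite(kas) || kas <= 0) stop("kas must be > 0")
  if (p0_act < 0) stop("p0_act must be >= 0")
  if (delta_f < 0) stop("delta_f must be >= 0 for a quenching system")
  if (f_lig < 0) stop("f_lig must be >= 0")
  structure(list(kas = kas, p0_act = p0_act, f0 = f0,
                 delta_f = delta_f, f_lig = f_lig),
            class = "binding_parameters")
}

#' Equilibrium complex concentration under ligand depletion
#'
#' Solves the mass-action equilibrium `Kas = [PL] / ([P][L])` with
#' `[P] = p0_act - [PL]` and `[L] = ligand_total - [PL]`, i.e. the
#' quadratic (ligand-depletion) isotherm required when bound ligand is a
#' non-negligible fraction of total:
#' `[PL] = (b - sqrt(b^2 - 4 p0 L0)) / 2`, `b = p0 + L0 + 1/Kas`.
#' Computed in the algebraically equivalent form
#' `2 p0 L0 / (b + sqrt(b^2 - 4 p0 L0))`, which avoids catastrophic
#' cancellation in the tight-binding limit (stable up to `kas ~ 1e9`).
#'
#' @param kas association constant, uM^-1; > 0.
#' @param p0_act total active protein, uM; >= 0.
#' @param ligand_total total ligand, uM; numeric vector, each >= 0.
#' @return `[PL]` in uM, bounded by `0 <= [PL] <= min(p0_act, ligand_total)`.
#' @examples
#' complex_concentration(1, 1, 1)      # 0.381966...
#' complex_concentration(1e9, 0.1, 5)  # stoichiometric limit 0.1
#' @export
complex_concentration <- function(kas, p0_act, ligand_total) {
  if (!is.finite(kas) || kas <= 0) stop("kas must be > 0")
  if (!is.finite(p0_act) || p0_act < 0) stop("p0_act must be >= 0")
  if (any(!is.finite(ligand_total)) || any(ligand_total < 0))
    stop("ligand_total must be >= 0")
  b <- p0_act + ligand_total + 1 / kas
  disc <- b^2 - 4 * p0_act * ligand_total
  disc[disc < 0] <- 0  # guard roundoff at exact stoichiometric equality
  2 * p0_act * ligand_total / (b + sqrt(disc))
}

#' Model fluorescence at a total ligand concentration
#'
#' @param params a [binding_parameters()] object.
#' @param ligand_total total ligand, uM; numeric vector.
#' @return fluorescence in arbitrary units; `F(0) = f0`, and the slope
#'   tends to `f_lig` once the protein is saturated (free-cap emission
#'   dominating at high concentrations).
#' @export
model_fluorescence <- function(params, ligand_total) {
  stopifnot(inherits(params, "binding_parameters"))
  pl <- complex_concentration(params$kas, params$p0_act, ligand_total)
  params$f0 - params$delta_f * pl + params$f_lig * (ligand_total - pl)
}

#' Correct raw fluorescence for dilution and the inner filter effect
#'
#' `F_corr = F_raw * (volume / reference_volume) * 10^((A_ex + A_em)/2)`.
#' The dilution factor rescales the signal to the reference (initial)
#' sample volume; the inner-filter factor is the standard half-path
#' absorbance correction for attenuation of excitation and emission by the
#' absorbing ligand. Missing volumes behave as `volume = reference_volume`
#' and missing absorbances as zero, so the function is the identity when
#' all optional fields are absent.
#'
#' @param fluorescence_raw raw intensities, arbitrary units.
#' @param volume cumulative sample volume per point, uL, or `NULL`/`NA`.
#' @param a_ex,a_em absorbance at the excitation/emission wavelength,
#'   or `NULL`/`NA` (treated as 0).
#' @param reference_volume reference volume, uL; must be > 0 and <= every
#'   supplied volume (titration only adds volume).
#' @return corrected fluorescence vector.
#' @examples
#' correct_intensities(100, a_ex = 0.1, a_em = 0.05)      # 118.85
#' correct_intensities(100, volume = 1540, reference_volume = 1400)  # 110
#' @export
correct_intensities <- function(fluorescence_raw, volume = NULL,
                                a_ex = NULL, a_em = NULL,
                                reference_volume = 1) {
  n <- length(fluorescence_raw)
  if (any(fluorescence_raw < 0)) stop("fluorescence_raw must be >= 0")
  if (!is.finite(reference_volume) || reference_volume <= 0)
    stop("reference_volume must be > 0")
  vol <- if (is.null(volume)) rep(reference_volume, n) else {
    v <- as.numeric(volume); v[is.na(v)] <- reference_volume; v
  }
  if (any(vol < reference_volume - 1e-9))
    stop("volume below reference_volume: titrations only add volume")
  ax <- if (is.null(a_ex)) 0 else { a <- as.numeric(a_ex); a[is.na(a)] <- 0; a }
  ae <- if (is.null(a_em)) 0 else { a <- as.numeric(a_em); a[is.na(a)] <- 0; a }
  if (any(ax < 0) || any(ae < 0)) stop("absorbances must be >= 0")
  fluorescence_raw * (vol / reference_volume) * 10^((ax + ae) / 2)
}

#' Construct a titration curve
#'
#' One fluorescence titration experiment: protein and ligand identity,
#' conditions, and the ordered table of points. Points must start at zero
#' ligand (the apo-protein baseline) and be non-decreasing in total ligand.
#'
#' @param protein_id text identifier, e.g. `"heIF4E1a"`.
#' @param ligand cap-analogue name (see [parse_analogue_name()]).
#' @param points data frame with columns `ligand_total` (uM),
#'   `fluorescence_raw`, and optionally `volume` (uL), `a_ex`, `a_em`.
#' @param temperature kelvin.
#' @param buffer_tag text tag recording buffer composition (notably
#'   glycerol presence, which itself shifts affinities).
#' @param excitation_nm,observation_nm wavelengths, nm.
#' @return an object of class `titration_curve`.
#' @export
titration_curve <- function(protein_id, ligand, points,
                            temperature = 293.15,
                            buffer_tag = "standard",
                            excitation_nm = 280, observation_nm = 337) {
  points <- as.data.frame(points)
  req <- c("ligand_total", "fluorescence_raw")
  if (!all(req %in% names(points)))
    stop("points must have columns: ", paste(req, collapse = ", "))
  if (nrow(points) < 6)
    stop("a titration curve needs at least 6 points, got ", nrow(points))
  if (points$ligand_total[1] != 0)
    stop("the first point must be the zero-ligand baseline")
  if (any(diff(points$ligand_total) < 0))
    stop("ligand_total must be non-decreasing across points")
  if (any(points$ligand_total < 0) || any(points$fluorescence_raw < 0))
    stop("ligand_total and fluorescence_raw must be >= 0")
  structure(list(protein_id = protein_id, ligand = ligand,
                 temperature = temperature, buffer_tag = buffer_tag,
                 excitation_nm = excitation_nm,
                 observation_nm = observation_nm,
                 points = points),
            class = "titration_curve")
}

#' @export
print.titration_curve <- function(x, ...) {
  cat(sprintf("<titration_curve> %s + %s (%s, %.2f K), %d points, L0 %g-%g uM\n",
              x$protein_id, x$ligand, x$buffer_tag, x$temperature,
              nrow(x$points), min(x$points$ligand_total),
              max(x$points$ligand_total)))
  invisible(x)
}

#' Apply intensity corrections to a whole curve
#'
#' Convenience wrapper around [correct_intensities()]: corrects every
#' point of a curve, taking the first point's volume as the reference.
#'
#' @param curve a [titration_curve()].
#' @return the curve with `points$fluorescence_raw` replaced by corrected
#'   values (and the optional columns dropped from further influence).
#' @export
correct_titration <- function(curve) {
  stopifnot(inherits(curve, "titration_curve"))
  p <- curve$points
  ref <- if ("volume" %in% names(p) && is.finite(p$volume[1])) p$volume[1] else 1
  p$fluorescence_raw <- correct_intensities(
    p$fluorescence_raw,
    volume = if ("volume" %in% names(p)) p$volume else NULL,
    a_ex = if ("a_ex" %in% names(p)) p$a_ex else NULL,
    a_em = if ("a_em" %in% names(p)) p$a_em else NULL,
    reference_volume = ref)
  p$volume <- NULL; p$a_ex <- NULL; p$a_em <- NULL
  curve$points <- p
  curve
}

#' Read a titration curve from CSV
#'
#' Expects mandatory header columns `ligand_total_uM` and `fluorescence`,
#' optional `volume_uL`, `a_ex`, `a_em`. Curve-level metadata may precede
#' the header as a `#`-prefixed YAML comment block, e.g.
#' `# protein_id: heIF4E1a`.
#'
#' @param path CSV file path.
#' @return a [titration_curve()].
#' @export
read_titration_csv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- if (length(meta_lines)) {
    yaml::yaml.load(paste(sub("^#\\s?", "", meta_lines), collapse = "\n"))
  } else list()
  tab <- read.csv(text = paste(grep("^#", lines, invert = TRUE, value = TRUE),
                               collapse = "\n"))
  req <- c("ligand_total_uM", "fluorescence")
  if (!all(req %in% names(tab)))
    stop("titration CSV must have columns: ", paste(req, collapse = ", "))
  points <- data.frame(ligand_total = tab$ligand_total_uM,
                       fluorescence_raw = tab$fluorescence)
  if ("volume_uL" %in% names(tab)) points$volume <- tab$volume_uL
  if ("a_ex" %in% names(tab)) points$a_ex <- tab$a_ex
  if ("a_em" %in% names(tab)) points$a_em <- tab$a_em
  defaults <- list(protein_id = "unknown", ligand = "unknown",
                   temperature = 293.15, buffer_tag = "standard",
                   excitation_nm = 280, observation_nm = 337)
  meta <- modifyList(defaults, meta[names(meta) %in% names(defaults)])
  titration_curve(meta$protein_id, meta$ligand, points,
                  temperature = meta$temperature,
                  buffer_tag = meta$buffer_tag,
                  excitation_nm = meta$excitation_nm,
                  observation_nm = meta$observation_nm)
}

#' Write a titration curve to CSV
#'
#' Inverse of [read_titration_csv()]: metadata in a `#`-prefixed YAML
#' comment block, then the point table.
#'
#' @param curve a [titration_curve()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_titration_csv <- function(curve, path) {
  stopifnot(inherits(curve, "titration_curve"))
  meta <- curve[c("protein_id", "ligand", "temperature", "buffer_tag",
                  "excitation_nm", "observation_nm")]
  header <- paste0("# ", strsplit(yaml::as.yaml(meta), "\n")[[1]])
  p <- curve$points
  tab <- data.frame(ligand_total_uM = p$ligand_total,
                    fluorescence = p$fluorescence_raw)
  if ("volume" %in% names(p)) tab$volume_uL <- p$volume
  if ("a_ex" %in% names(p)) tab$a_ex <- p$a_ex
  if ("a_em" %in% names(p)) tab$a_em <- p$a_em
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(header, con)
  write.csv(tab, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
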