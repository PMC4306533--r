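#' Standard Gibbs free energy of binding
#'
#' `delta_g = -R T ln(Kas)` with the association constant converted from
#' uM^-1 to M^-1 (standard state 1 M), `R = 1.9872041e-3` kcal/(mol K).
#'
#' @param kas association constant, uM^-1; > 0.
#' @param temperature kelvin; default 293.15 K (20 C, the usual
#'   titration temperature for these proteins).
#' @return free energy of association, kcal/mol (negative for favourable
#'   binding).
#' @examples
#' delta_g(68.4)        # about -10.51 kcal/mol
#' delta_g(1e-6)        # Kas = 1 M^-1 -> 0
#' @export
delta_g <- function(kas, temperature = 293.15) {
  if (any(!is.finite(kas)) || any(kas <= 0)) stop("kas must be > 0")
  if (temperature <= 0) stop("temperature must be > 0 K")
  -R_KCAL * temperature * log(kas * 1e6)
}

.check_record <- function(rec) {
  req <- c("protein_id", "ligand", "buffer_tag", "kas", "kas_se")
  if (!all(req %in% names(rec)))
    stop("affinity record needs fields: ", paste(req, collapse = ", "))
  if (!is.finite(rec$kas) || rec$kas <= 0) stop("record kas must be > 0")
  rec
}

#' Free-energy change for a ligand transition
#'
#' For one protein, the change in standard binding free energy when ligand
#' A is replaced by ligand B: `ddg = -R T ln(kas_B / kas_A)` (the uM^-1
#' scale cancels in the ratio). Uncertainty by first-order propagation of
#' independent relative errors:
#' `ddg_se = R T sqrt((se_A/kas_A)^2 + (se_B/kas_B)^2)`. A negative value
#' is an energy gain (B binds tighter than A).
#'
#' @param rec_from,rec_to affinity records (lists or single data-frame
#'   rows) with fields `protein_id`, `ligand`, `buffer_tag`, `kas`,
#'   `kas_se`; both must share protein and buffer, since affinities are
#'   only comparable within a buffer.
#' @param temperature kelvin.
#' @return an object of class `transition_energy`: `protein_id`,
#'   `from_ligand`, `to_ligand`, `ddg`, `ddg_se` (kcal/mol),
#'   `temperature`.
#' @export
delta_delta_g <- function(rec_from, rec_to, temperature = 293.15) {
  rec_from <- .check_record(as.list(rec_from))
  rec_to <- .check_record(as.list(rec_to))
  if (!identical(rec_from$protein_id, rec_to$protein_id))
    stop("transition records must share protein_id (",
         rec_from$protein_id, " vs ", rec_to$protein_id, ")")
  if (!identical(rec_from$buffer_tag, rec_to$buffer_tag))
    stop("transition records must share buffer_tag (",
         rec_from$buffer_tag, " vs ", rec_to$buffer_tag,
         "); affinities are not comparable across buffers")
  rt <- R_KCAL * temperature
  ddg <- -rt * log(rec_to$kas / rec_from$kas)
  ddg_se <- rt * sqrt((rec_from$kas_se / rec_from$kas)^2 +
                      (rec_to$kas_se / rec_to$kas)^2)
  structure(list(protein_id = rec_from$protein_id,
                 from_ligand = rec_from$ligand,
                 to_ligand = rec_to$ligand,
                 ddg = ddg, ddg_se = ddg_se,
                 temperature = temperature),
            class = "transition_energy")
}

#' @export
print.transition_energy <- function(x, ...) {
  cat(sprintf("<transition_energy> %s: %s -> %s  ddG = %.3f +/- %.3f kcal/mol\n",
              x$protein_id, x$from_ligand, x$to_ligand, x$ddg, x$ddg_se))
  invisible(x)
}

#' Affinity ratio between two proteins for the same ligand
#'
#' The dimensionless ratio `kas_a / kas_b`, the standard summary of how
#' much better one paralog binds a given cap analogue than the other
#' (e.g. eIF4E1a over eIF4E1b). The raw value is returned; reporting
#' layers round to two decimals with [format_ratio()].
#'
#' @param rec_a,rec_b affinity records with positive `kas`.
#' @return numeric ratio.
#' @export
affinity_ratio <- function(rec_a, rec_b) {
  rec_a <- as.list(rec_a); rec_b <- as.list(rec_b)
  if (!is.finite(rec_a$kas) || rec_a$kas <= 0 ||
      !is.finite(rec_b$kas) || rec_b$kas <= 0)
    stop("affinity_ratio needs positive kas in both records")
  rec_a$kas / rec_b$kas
}

#' Round a ratio for display
#'
#' Two decimals, round-half-even (base R convention), matching the usual
#' presentation of affinity-ratio columns.
#'
#' @param x numeric ratio.
#' @return numeric rounded to 2 decimals.
#' @export
format_ratio <- function(x) round(x, 2)

#' Build a ligand-transition free-energy table
#'
#' Applies [delta_delta_g()] to every requested ligand transition for
#' every protein x buffer group present in the affinity table. Cells
#' where either ligand is unmeasured for that protein are emitted as
#' explicit gaps (`NA` energies), mirroring the em-dashes of a printed
#' transition table rather than being dropped.
#'
#' @param records data frame of affinity records (`protein_id`, `ligand`,
#'   `buffer_tag`, `kas`, `kas_se`).
#' @param transitions data frame with columns `from` and `to` (ligand
#'   names); every named ligand must be measured for at least one
#'   protein.
#' @param temperature kelvin.
#' @return data frame: `protein_id`, `buffer_tag`, `from_ligand`,
#'   `to_ligand`, `ddg`, `ddg_se` (kcal/mol; `NA` for gap cells).
#' @export
build_ddg_table <- function(records, transitions, temperature = 293.15) {
  records <- as.data.frame(records)
  transitions <- as.data.frame(transitions)
  if (nrow(transitions) == 0L)
    return(data.frame(protein_id = character(), buffer_tag = character(),
                      from_ligand = character(), to_ligand = character(),
                      ddg = numeric(), ddg_se = numeric(),
                      stringsAsFactors = FALSE))
  if (!all(c("from", "to") %in% names(transitions)))
    stop("transitions must have columns 'from' and 'to'")
  unknown <- setdiff(unique(c(transitions$from, transitions$to)),
                     unique(records$ligand))
  if (length(unknown))
    stop("transitions name ligand(s) absent from the affinity table: ",
         paste(unknown, collapse = ", "))

  groups <- unique(records[, c("protein_id", "buffer_tag")])
  rows <- list()
  for (g in seq_len(nrow(groups))) {
    sub <- records[records$protein_id == groups$protein_id[g] &
                   records$buffer_tag == groups$buffer_tag[g], ]
    for (t in seq_len(nrow(transitions))) {
      from <- sub[sub$ligand == transitions$from[t], ]
      to <- sub[sub$ligand == transitions$to[t], ]
      if (nrow(from) == 1L && nrow(to) == 1L) {
        te <- delta_delta_g(from, to, temperature)
        ddg <- te$ddg; ddg_se <- te$ddg_se
      } else {
        ddg <- NA_real_; ddg_se <- NA_real_  # gap cell
      }
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = groups$protein_id[g],
        buffer_tag = groups$buffer_tag[g],
        from_ligand = transitions$from[t],
        to_ligand = transitions$to[t],
        ddg = ddg, ddg_se = ddg_se, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Published equilibrium association constants
#'
#' The pooled association constants (uM^-1, with standard errors) for
#' complexes of human and Xenopus eIF4E1a/eIF4E1b proteins with the cap
#' analogue panel, as determined by fluorescence titration at 20 C.
#' `buffer_tag` separates the standard buffer from the 10%-glycerol
#' buffer used to stabilize the Xenopus eIF4E1b N-terminal truncation
#' (glycerol itself lowers cap affinities up to ~2-fold, so the two are
#' not directly comparable).
#'
#' @param path TSV file; default is the bundled table.
#' @return data frame: `protein_id`, `ligand`, `buffer_tag`, `kas`,
#'   `kas_se`.
#' @export
published_kas_table <- function(path = system.file(
    "extdata", "eif4e_kas_published.tsv", package = "capaffinity")) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Published ligand-transition free energies
#'
#' The published transition table (kcal/mol, 20 C) matching
#' [published_kas_table()]; used as the reference in reproduction checks.
#'
#' @param path TSV file; default is the bundled table.
#' @return data frame: `protein_id`, `buffer_tag`, `from_ligand`,
#'   `to_ligand`, `ddg`, `ddg_se` (`NA` for gap cells).
#' @export
published_ddg_table <- function(path = system.file(
    "extdata", "eif4e_ddg_published.tsv", package = "capaffinity")) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Canonical ligand-transition list
#'
#' The standard set of cap-structure transitions: guanine-ring
#' modifications, phosphate-chain elongation, and second-nucleotide /
#' ribose-methylation steps.
#'
#' @param path TSV file; default is the bundled list.
#' @return data frame with columns `block`, `from`, `to`.
#' @export
cap_transitions <- function(path = system.file(
    "extdata", "cap_transitions.tsv", package = "capaffinity")) {
  read.delim(path, stringsAsFactors = FALSE)
}
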