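#' Construct a family-labelled multiple alignment
#'
#' @param sequences named character vector of aligned sequences (equal
#'   lengths, gaps as `-`); names are sequence ids.
#' @param families named character/factor vector mapping every id to a
#'   family label (two families, conventionally `"A"` and `"B"`).
#' @param reference_id id of the sequence whose ungapped coordinates are
#'   used for reported residue numbering; defaults to the first id.
#' @return object of class `labelled_alignment` with a character matrix
#'   `mat` (rows = sequences), `ids`, `families`, `reference_id`.
#' @export
labelled_alignment <- function(sequences, families,
                               reference_id = names(sequences)[1]) {
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
    stop("sequences must be named by id")
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L)
    stop("aligned rows have unequal lengths: ",
         paste(range(lens), collapse = "-"))
  missing_lab <- setdiff(names(sequences), names(families))
  if (length(missing_lab))
    stop("unlabelled sequence(s): ", paste(missing_lab, collapse = ", "))
  if (!reference_id %in% names(sequences))
    stop("reference_id '", reference_id, "' not in the alignment")
  mat <- do.call(rbind, strsplit(toupper(sequences), ""))
  rownames(mat) <- names(sequences)
  structure(list(mat = mat, ids = names(sequences),
                 families = as.character(families[names(sequences)]),
                 reference_id = reference_id),
            class = "labelled_alignment")
}

#' @export
print.labelled_alignment <- function(x, ...) {
  cat(sprintf("<labelled_alignment> %d sequences x %d columns (%s); reference %s\n",
              nrow(x$mat), ncol(x$mat),
              paste(sprintf("%s: %d", names(table(x$families)),
                            table(x$families)), collapse = ", "),
              x$reference_id))
  invisible(x)
}

#' Read a family-labelled alignment from file
#'
#' Reads an aligned FASTA or Clustal file (via
#' [Biostrings::readAAMultipleAlignment()]) and attaches family labels.
#' The same alignment read from either encoding yields an identical
#' object.
#'
#' @param path alignment file.
#' @param format `"fasta"` (aligned) or `"clustal"`.
#' @param labels family labels: a data frame with columns `id` and
#'   `family`, a path to such a TSV, or a named character vector.
#' @param reference_id numbering reference; default first sequence.
#' @return a [labelled_alignment()].
#' @export
read_alignment <- function(path, format = c("fasta", "clustal"),
                           labels, reference_id = NULL) {
  format <- match.arg(format)
  msa <- Biostrings::readAAMultipleAlignment(path, format = format)
  seqs <- as.character(Biostrings::unmasked(msa))
  if (is.character(labels) && length(labels) == 1L && file.exists(labels))
    labels <- read.delim(labels, stringsAsFactors = FALSE)
  if (is.data.frame(labels)) {
    if (!all(c("id", "family") %in% names(labels)))
      stop("labels table must have columns 'id' and 'family'")
    labels <- setNames(labels$family, labels$id)
  }
  if (is.null(reference_id)) reference_id <- names(seqs)[1]
  labelled_alignment(seqs, labels, reference_id = reference_id)
}

#' Write an alignment as aligned FASTA
#'
#' @param aln a [labelled_alignment()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "labelled_alignment"))
  seqs <- apply(aln$mat, 1, paste, collapse = "")
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  invisible(path)
}

# Ungapped reference position for each alignment column; NA where the
# reference itself is gapped.
.reference_positions <- function(aln) {
  ref <- aln$mat[aln$reference_id, ]
  pos <- cumsum(ref != "-")
  pos[ref == "-"] <- NA_integer_
  pos
}

.column_consensus <- function(residues, gap_policy) {
  if (gap_policy == "strict") {
    if (any(residues == "-")) return(c(res = NA_character_, frac = NA))
  } else {
    residues <- residues[residues != "-"]
    if (length(residues) == 0L) return(c(res = NA_character_, frac = NA))
  }
  tab <- sort(table(residues), decreasing = TRUE)
  c(res = names(tab)[1], frac = as.numeric(tab[1]) / length(residues))
}

#' Find family-discriminating alignment positions
#'
#' Scans every alignment column for the signature of a paralog-family
#' discriminating residue: the modal residue within each family reaches
#' the conservation threshold, and the two family consensus residues
#' differ. With the default strict policy (threshold 1.0, any in-family
#' gap disqualifies the column) this is exact within-family identity —
#' the conservative reading of "conserved and dispersed residue changes
#' that distinguish two families"; the `"exclude"` policy instead drops
#' gapped rows before computing conservation.
#'
#' @param aln a [labelled_alignment()] with >= 2 sequences per family.
#' @param threshold minimum within-family modal-residue fraction, in
#'   (0.5, 1].
#' @param gap_policy `"strict"` (default) or `"exclude"`; see above.
#' @param annotation optional named integer vector of functional-site
#'   residues in reference numbering (e.g. from [site_annotations()]);
#'   positions within `annotation_window` of an annotated residue are
#'   tagged in the `near_site` column.
#' @param annotation_window half-width, in residues, for `near_site`
#'   tagging.
#' @return data frame sorted by reference numbering: `column` (1-based
#'   alignment column), `ref_position`, `consensus_a`, `consensus_b`,
#'   `conservation_a`, `conservation_b`, `near_site`.
#' @export
find_discriminating_positions <- function(aln, threshold = 1.0,
                                          gap_policy = c("strict", "exclude"),
                                          annotation = NULL,
                                          annotation_window = 2L) {
  stopifnot(inherits(aln, "labelled_alignment"))
  gap_policy <- match.arg(gap_policy)
  if (threshold <= 0.5 || threshold > 1)
    stop("threshold must lie in (0.5, 1]")
  fams <- sort(unique(aln$families))
  if (length(fams) != 2L)
    stop("exactly two families are required, got: ",
         paste(fams, collapse = ", "))
  for (f in fams)
    if (sum(aln$families == f) < 2L)
      stop("family '", f, "' has fewer than 2 sequences")
  rows_a <- aln$families == fams[1]
  rows_b <- aln$families == fams[2]
  ref_pos <- .reference_positions(aln)

  hits <- list()
  for (j in seq_len(ncol(aln$mat))) {
    ca <- .column_consensus(aln$mat[rows_a, j], gap_policy)
    cb <- .column_consensus(aln$mat[rows_b, j], gap_policy)
    if (is.na(ca[["res"]]) || is.na(cb[["res"]])) next
    fa <- as.numeric(ca[["frac"]]); fb <- as.numeric(cb[["frac"]])
    if (fa + 1e-12 < threshold || fb + 1e-12 < threshold) next
    if (ca[["res"]] == cb[["res"]]) next
    hits[[length(hits) + 1L]] <- data.frame(
      column = j, ref_position = ref_pos[j],
      consensus_a = ca[["res"]], consensus_b = cb[["res"]],
      conservation_a = fa, conservation_b = fb,
      near_site = NA_character_, stringsAsFactors = FALSE)
  }
  if (length(hits) == 0L)
    return(data.frame(column = integer(), ref_position = integer(),
                      consensus_a = character(), consensus_b = character(),
                      conservation_a = numeric(), conservation_b = numeric(),
                      near_site = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  if (!is.null(annotation) && length(annotation)) {
    ann_pos <- as.integer(annotation)
    ann_lab <- if (is.null(names(annotation)))
      as.character(ann_pos) else names(annotation)
    out$near_site <- vapply(out$ref_position, function(p) {
      if (is.na(p)) return(NA_character_)
      d <- abs(ann_pos - p)
      if (min(d) <= annotation_window) ann_lab[which.min(d)]
      else NA_character_
    }, character(1))
  }
  out <- out[order(is.na(out$ref_position), out$ref_position, out$column), ]
  rownames(out) <- NULL
  out
}

#' Net charge of an N-terminal window
#'
#' Counts +1 per lysine or arginine and -1 per aspartate or glutamate in
#' the first `window` residues (histidine configurable). The default
#' 27-residue window matches the unstructured N-terminal region that
#' distinguishes the basic eIF4E1b N-termini from the acidic eIF4E1a
#' ones.
#'
#' @param sequence ungapped residue string (one-letter codes).
#' @param window number of leading residues to score; must not exceed
#'   the sequence length.
#' @param his_charge charge assigned to histidine, 0 (default) or +1.
#' @return signed integer net charge.
#' @examples
#' nterm_charge("MKKRDE", window = 6)  # +1
#' @export
nterm_charge <- function(sequence, window = 27L, his_charge = 0) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (window > nchar(sequence))
    stop("window (", window, ") exceeds sequence length (",
         nchar(sequence), ")")
  if (window == 0L) return(0L)
  res <- strsplit(toupper(substr(sequence, 1, window)), "")[[1]]
  valid <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  bad <- setdiff(res, valid)
  if (length(bad))
    stop("non-residue character(s) in sequence: ",
         paste(unique(bad), collapse = ", "))
  as.integer(sum(res %in% c("K", "R")) - sum(res %in% c("D", "E")) +
             his_charge * sum(res == "H"))
}

#' Map a residue number between numbering conventions
#'
#' Closely related paralogs and orthologs are conveniently discussed in a
#' common numbering, related by a constant offset (e.g. the Xenopus
#' eIF4E1a numbering runs 4 behind the human eIF4E1a / Xenopus eIF4E1b
#' convention, so Trp98 in XeIF4E1a is Trp102 elsewhere).
#'
#' @param position residue number(s), 1-based.
#' @param offset signed offset to add.
#' @return mapped position(s); errors if any result is < 1.
#' @examples
#' map_numbering(98, 4)   # 102
#' @export
map_numbering <- function(position, offset) {
  out <- as.integer(position) + as.integer(offset)
  if (any(out < 1L))
    stop("mapped position(s) below 1: numbering offsets must keep ",
         "positions in the mature sequence")
  out
}

#' Bundled numbering-offset table
#'
#' Pairwise constant offsets between the numbering conventions of the
#' proteins discussed in this package (`to_position = from_position +
#' offset`).
#'
#' @param path TSV file; default bundled table.
#' @return data frame: `from_protein`, `to_protein`, `offset`.
#' @export
numbering_offsets <- function(path = system.file(
    "extdata", "numbering_offsets.tsv", package = "capaffinity")) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Functional-site annotation of the eIF4E1a reference numbering
#'
#' Editable YAML annotation keyed to human eIF4E1a numbering: the
#' cap-binding pocket residues (tryptophan sandwich, the glutamate that
#' hydrogen-bonds N2 of guanine, phosphate-chain binders and the
#' C-terminal loop) and an illustrative set of residues on the
#' eIF4G/4E-BP-binding helix face.
#'
#' @param path YAML file; default bundled annotation.
#' @return named integer vector (names are residue labels like `"W102"`).
#' @export
site_annotations <- function(path = system.file(
    "extdata", "site_annotations.yaml", package = "capaffinity")) {
  raw <- yaml::read_yaml(path)
  out <- integer(0)
  for (cls in raw)
    for (site in cls$residues)
      out[site$label] <- as.integer(site$position)
  out
}
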