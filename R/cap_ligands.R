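#' Construct a cap-analogue description
#'
#' A `cap_analogue` records the chemistry of a mono- or dinucleotide cap
#' analogue: the N7 substituent on the guanine ring (the group that creates
#' the positive charge needed for cation-pi stacking in the eIF4E pocket),
#' N2 dimethylation, the number of phosphate groups, an optional second
#' nucleoside and optional 2'-O ribose methylation, plus the ionization
#' model used by [net_charge()].
#'
#' @param name canonical text label, e.g. `"m7GTP"`.
#' @param n7_mod N7 substituent: `"none"`, `"methyl"`, `"ethyl"` or
#'   `"benzyl"`.
#' @param n2_methyls number of N2 methyl groups, 0 or 2 (2 only together
#'   with N7-methyl, i.e. the trimethylated cap of snRNAs).
#' @param phosphate_count number of phosphates, 1 to 5.
#' @param second_nucleoside `"none"`, `"G"` or `"A"`.
#' @param ribose_2O_methyl 2'-O methylation: `"none"`, `"first"` or
#'   `"second"` (which ribose carries it); only meaningful for
#'   dinucleotides.
#' @param base_charge reference net charge with all modelled ionizable
#'   groups protonated (the low-pH limit of [net_charge()]).
#' @param ionizable_groups list of groups from [ionizable_group()].
#' @return an object of class `cap_analogue`.
#' @seealso [parse_analogue_name()], [cap_catalogue()], [net_charge()]
#' @export
cap_analogue <- function(name,
                         n7_mod = "none",
                         n2_methyls = 0L,
                         phosphate_count = 3L,
                         second_nucleoside = "none",
                         ribose_2O_methyl = "none",
                         base_charge = NA_real_,
                         ionizable_groups = list()) {
  n7_mod <- match.arg(n7_mod, c("none", "methyl", "ethyl", "benzyl"))
  second_nucleoside <- match.arg(second_nucleoside, c("none", "G", "A"))
  ribose_2O_methyl <- match.arg(ribose_2O_methyl, c("none", "first", "second"))
  n2_methyls <- as.integer(n2_methyls)
  phosphate_count <- as.integer(phosphate_count)

  if (!phosphate_count %in% 1:5)
    stop("phosphate_count must be between 1 and 5, got ", phosphate_count)
  if (!n2_methyls %in% c(0L, 2L))
    stop("n2_methyls must be 0 or 2, got ", n2_methyls)
  if (n2_methyls == 2L && n7_mod != "methyl")
    stop("N2 dimethylation only occurs together with N7-methyl (m227G core)")
  if (second_nucleoside == "none" && ribose_2O_methyl != "none")
    stop("ribose 2'-O methylation requires a second nucleoside")
  for (g in ionizable_groups) {
    if (!inherits(g, "ionizable_group"))
      stop("ionizable_groups must be built with ionizable_group()")
  }

  structure(
    list(name = name, n7_mod = n7_mod, n2_methyls = n2_methyls,
         phosphate_count = phosphate_count,
         second_nucleoside = second_nucleoside,
         ribose_2O_methyl = ribose_2O_methyl,
         base_charge = as.numeric(base_charge),
         ionizable_groups = ionizable_groups),
    class = "cap_analogue")
}

#' Describe one ionizable group of a cap analogue
#'
#' @param label text label, e.g. `"N1-H (m7G)"`.
#' @param pKa acid dissociation constant, pH units, in (0, 14).
#' @param deprotonated_delta signed charge change on deprotonation
#'   (-1 for an acid losing a proton).
#' @return an object of class `ionizable_group`.
#' @export
ionizable_group <- function(label, pKa, deprotonated_delta = -1L) {
  pKa <- as.numeric(pKa)
  if (!is.finite(pKa) || pKa <= 0 || pKa >= 14)
    stop("pKa must lie strictly between 0 and 14, got ", pKa)
  structure(list(label = label, pKa = pKa,
                 deprotonated_delta = as.integer(deprotonated_delta)),
            class = "ionizable_group")
}

#' @export
format.cap_analogue <- function(x, ...) canonical_name(x)

#' @export
print.cap_analogue <- function(x, ...) {
  cat("<cap_analogue> ", canonical_name(x), "\n",
      "  N7: ", x$n7_mod,
      if (x$n2_methyls > 0) sprintf(", N2: %d methyls", x$n2_methyls) else "",
      "; phosphates: ", x$phosphate_count,
      "; second nucleoside: ", x$second_nucleoside,
      if (x$ribose_2O_methyl != "none")
        paste0(" (2'-O-methyl on ", x$ribose_2O_methyl, " ribose)") else "",
      "\n", sep = "")
  if (length(x$ionizable_groups))
    cat("  base charge ", x$base_charge, "; ",
        length(x$ionizable_groups), " ionizable group(s)\n", sep = "")
  invisible(x)
}

.N7_PREFIX <- c(none = "", methyl = "m7", ethyl = "et7", benzyl = "bn7")
.PHOS_SUFFIX <- c("MP", "DP", "TP", "p4", "p5")

#' Canonical text label of a cap analogue
#'
#' Renders the chemistry fields back into the label grammar understood by
#' [parse_analogue_name()]; the composition of the two functions is the
#' identity on every analogue of the shipped catalogue.
#'
#' @param analogue a `cap_analogue`.
#' @return character scalar.
#' @export
canonical_name <- function(analogue) {
  stopifnot(inherits(analogue, "cap_analogue"))
  prefix <- if (analogue$n2_methyls == 2L) "m227" else .N7_PREFIX[[analogue$n7_mod]]
  if (analogue$second_nucleoside == "none") {
    paste0(prefix, "G", .PHOS_SUFFIX[analogue$phosphate_count])
  } else {
    paste0(prefix, "G",
           if (analogue$ribose_2O_methyl == "first") "2O" else "",
           paste(rep("p", analogue$phosphate_count), collapse = ""),
           if (analogue$ribose_2O_methyl == "second") "m2O" else "",
           analogue$second_nucleoside)
  }
}

#' Parse a cap-analogue name
#'
#' Understands the label grammar covering the ligand panel of this kind of
#' study: an optional N7 prefix (`m7`, `et7`, `bn7`, or `m227` for the
#' N2,N2,N7-trimethylated cap), the guanosine core `G`, and either a
#' mononucleotide phosphate code (`MP`/`DP`/`TP`/`p4`/`p5`) or a
#' dinucleotide tail `ppp` + second base (`G` or `A`). 2'-O ribose
#' methylation is flagged by a `2O` token after the first `G`
#' (`m7G2OpppG`) or an `m2O` token before the second base
#' (`m7Gpppm2OG`).
#'
#' @param name character scalar label.
#' @param catalogue optional catalogue from [cap_catalogue()]; when the
#'   name is present there, `base_charge` and `ionizable_groups` are
#'   filled in from it.
#' @return a [cap_analogue()].
#' @examples
#' parse_analogue_name("m7GTP")
#' parse_analogue_name("bn7GDP")
#' parse_analogue_name("m7G2OpppG")
#' @export
parse_analogue_name <- function(name, catalogue = NULL) {
  if (!is.character(name) || length(name) != 1L || is.na(name))
    stop("name must be a single character string")

  m <- regmatches(name, regexec(
    "^(m7|et7|bn7|m227)?G(2O)?(MP|DP|TP|p4|p5|(p{2,5})(m2O)?(G|A))$", name))[[1]]
  if (length(m) == 0L)
    stop("cannot parse cap-analogue name '", name, "'")
  prefix <- m[2]; ribose1 <- m[3]; tail <- m[4]
  bridge <- m[5]; ribose2 <- m[6]; second <- m[7]

  n7_mod <- switch(prefix, m7 = , m227 = "methyl", et7 = "ethyl",
                   bn7 = "benzyl", "none")
  n2 <- if (identical(prefix, "m227")) 2L else 0L

  if (nzchar(second)) {
    phos <- nchar(bridge)
    ribo <- if (nzchar(ribose1)) "first" else if (nzchar(ribose2)) "second" else "none"
    if (nzchar(ribose1) && nzchar(ribose2))
      stop("contradictory 2'-O methylation tokens in '", name, "'")
    out <- cap_analogue(name, n7_mod = n7_mod, n2_methyls = n2,
                        phosphate_count = phos, second_nucleoside = second,
                        ribose_2O_methyl = ribo)
  } else {
    if (nzchar(ribose1))
      stop("2'-O methylation token requires a dinucleotide in '", name, "'")
    phos <- match(tail, .PHOS_SUFFIX)
    out <- cap_analogue(name, n7_mod = n7_mod, n2_methyls = n2,
                        phosphate_count = phos)
  }

  if (!is.null(catalogue) && canonical_name(out) %in% names(catalogue)) {
    ref <- catalogue[[canonical_name(out)]]
    out$base_charge <- ref$base_charge
    out$ionizable_groups <- ref$ionizable_groups
  }
  out
}

#' Net charge of a cap analogue at a given pH
#'
#' Henderson-Hasselbalch model: each ionizable group contributes its
#' deprotonation charge change weighted by the fractional deprotonation
#' `1 / (1 + 10^(pKa - pH))`, independently of the other groups. The
#' result is `base_charge` in the low-pH limit and
#' `base_charge + sum(deltas)` in the high-pH limit, and is monotone
#' non-increasing in pH when every group is an acid.
#'
#' @param analogue a `cap_analogue` with `base_charge` and
#'   `ionizable_groups` populated (e.g. via [cap_catalogue()]).
#' @param pH numeric vector of pH values.
#' @return numeric vector of net charges, one per pH value.
#' @examples
#' cat <- cap_catalogue()
#' net_charge(cat[["m7GTP"]], 7.2)
#' @export
net_charge <- function(analogue, pH) {
  stopifnot(inherits(analogue, "cap_analogue"), is.numeric(pH))
  if (is.na(analogue$base_charge))
    stop("analogue '", analogue$name, "' has no base_charge; ",
         "populate it from a catalogue (see cap_catalogue())")
  q <- rep(analogue$base_charge, length(pH))
  for (g in analogue$ionizable_groups)
    q <- q + g$deprotonated_delta / (1 + 10^(g$pKa - pH))
  q
}

#' Load a cap-ligand catalogue
#'
#' Reads a YAML list of `{name, base_charge, groups: [{label, pKa,
#' delta}]}` entries into named `cap_analogue` objects. The default file
#' shipped with the package covers the full ligand panel; its pKa values
#' are illustrative literature-range numbers (the N1 proton of
#' N7-alkylguanosine and the secondary dissociation of the terminal
#' phosphate), supplied as editable configuration rather than measured
#' constants.
#'
#' @param path YAML file; default is the bundled catalogue.
#' @return named list of [cap_analogue()] objects.
#' @export
cap_catalogue <- function(path = system.file("extdata", "cap_catalogue.yaml",
                                             package = "capaffinity")) {
  raw <- yaml::read_yaml(path)
  out <- lapply(raw, function(entry) {
    groups <- lapply(entry$groups, function(g)
      ionizable_group(g$label, g$pKa, g$delta))
    a <- parse_analogue_name(entry$name)
    a$base_charge <- as.numeric(entry$base_charge)
    a$ionizable_groups <- groups
    a
  })
  setNames(out, vapply(out, canonical_name, character(1)))
}
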