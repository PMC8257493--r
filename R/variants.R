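AA3 <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C", Gln = "Q",
         Glu = "E", Gly = "G", His = "H", Ile = "I", Leu = "L", Lys = "K",
         Met = "M", Phe = "F", Pro = "P", Ser = "S", Thr = "T", Trp = "W",
         Tyr = "Y", Val = "V", Ter = "*")

PTV_CLASSES <- c("nonsense", "frameshift", "splice site", "deletion")
OTHER_CLASSES <- c("in-frame deletion", "complex indel", "duplication")

#' Parse a protein-level variant label
#'
#' Parses HGVS-style protein change labels such as `"p.R853Q"`,
#' `"p.Arg853Gln"`, `"p.R102*"` or `"p.T1420fs"` into reference amino acid,
#' 1-based protein position and alternate allele. Three-letter amino-acid
#' codes are normalized to one-letter form; `Ter`/`X` stops become `"*"`;
#' any frameshift suffix becomes `"fs"`.
#'
#' @param label Character vector of labels beginning with `"p."`.
#' @return A tibble with columns `label`, `ref_aa`, `position`, `alt`.
#' @examples
#' parse_protein_variant(c("p.R853Q", "p.Arg853Gln", "p.R102*"))
#' @export
parse_protein_variant <- function(label) {
  norm_aa <- function(x) {
    long <- x %in% names(AA3)
    x[long] <- unname(AA3[x[long]])
    x[x %in% c("X", "Ter")] <- "*"
    x
  }
  one <- function(lab) {
    if (!startsWith(lab, "p.")) {
      stop("not a protein-level (p.) label: ", lab, call. = FALSE)
    }
    body <- sub("^p\\.", "", lab)
    body <- gsub("[()]", "", body)
    m <- regmatches(body, regexec(
      "^([A-Z][a-z]{2}|[A-Z*])([0-9]+)(fs.*|[A-Z][a-z]{2}|[A-Z*]|\\*)$", body))[[1]]
    if (length(m) == 0L) stop("unparseable protein variant label: ", lab,
                              call. = FALSE)
    ref <- norm_aa(m[2])
    alt <- if (startsWith(m[4], "fs")) "fs" else norm_aa(m[4])
    pos <- as.integer(m[3])
    if (is.na(pos) || pos < 1L || !ref %in% AA3) {
      stop("unparseable protein variant label: ", lab, call. = FALSE)
    }
    tibble::tibble(label = lab, ref_aa = ref, position = pos, alt = alt)
  }
  dplyr::bind_rows(lapply(label, one))
}

#' Format a parsed protein change back to a one-letter label
#'
#' @param parsed Output of [parse_protein_variant()].
#' @return Character vector of labels in one-letter form, e.g. `"p.R853Q"`.
#' @export
format_protein_variant <- function(parsed) {
  paste0("p.", parsed$ref_aa, parsed$position, parsed$alt)
}

#' Collapse a detailed variant class to its broad class
#'
#' Frameshift, nonsense, splice site and (whole-gene) deletion variants are
#' protein-truncating (PTV); in-frame deletions, complex indels and
#' duplications are neither missense nor PTV and are excluded from
#' variant-class analyses.
#'
#' @param var_class Character vector drawn from `missense`, `nonsense`,
#'   `frameshift`, `splice site`, `in-frame deletion`, `complex indel`,
#'   `duplication`, `deletion`.
#' @return Character vector over `missense`, `PTV`, `other`.
#' @export
broad_class <- function(var_class) {
  known <- c("missense", PTV_CLASSES, OTHER_CLASSES)
  bad <- setdiff(unique(var_class), known)
  if (length(bad)) stop("unknown variant class token(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  dplyr::case_when(
    var_class == "missense" ~ "missense",
    var_class %in% PTV_CLASSES ~ "PTV",
    TRUE ~ "other"
  )
}

#' Read a protein topology table
#'
#' Reads a tab-separated feature table with columns `region`, `segment`,
#' `start`, `end` (1-based inclusive) describing an ion-channel topology:
#' transmembrane helices (`segment` = S1..S6 of a numbered domain),
#' intramembrane pore-forming features (`segment` = `"pore"`) and
#' cytoplasmic/extracellular stretches (`region` = `"cytoplasmic"` /
#' `"extracellular"`).
#'
#' A best-effort Na_V_1.2 topology ships with the package; see
#' [nav12_topology_path()]. Its interval boundaries are synthetic
#' (architecturally plausible, consistent with published recurrent-variant
#' locations) and boundary-sensitive results should be interpreted with
#' that in mind.
#'
#' @param file Path to the TSV file.
#' @return A tibble of class `protein_topology`.
#' @export
read_topology <- function(file) {
  df <- readr::read_tsv(file, show_col_types = FALSE, comment = "#")
  need <- c("region", "segment", "start", "end")
  if (!all(need %in% names(df))) {
    stop("topology table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(df$end < df$start)) stop("topology interval with end < start",
                                   call. = FALSE)
  mem <- df[!df$region %in% c("cytoplasmic", "extracellular"), ]
  if (nrow(mem) > 1) {
    o <- order(mem$start)
    if (any(mem$start[o][-1] <= mem$end[o][-nrow(mem)])) {
      stop("overlapping membrane features in topology", call. = FALSE)
    }
  }
  class(df) <- c("protein_topology", class(df))
  df
}

#' Locate a protein position in the channel topology
#'
#' Maps 1-based protein positions onto the topology: membrane features
#' (helices and pore-forming segments) take precedence over
#' cytoplasmic/extracellular stretches. Positions between the S5 and S6
#' helices of any domain additionally carry the derived S5-S6 pore-loop
#' flag, the region used for pore-loop association analyses (broader than
#' the intramembrane "pore-forming" feature itself).
#'
#' @param topology A [`protein_topology`][read_topology].
#' @param position Integer vector of 1-based protein positions.
#' @return A tibble with columns `position`, `domain` (e.g. `"DII"`, `NA`
#'   outside membrane features), `segment` (`"S1"`..`"S6"`, `"pore"`, `NA`),
#'   `label` (display label: `"Helical repeat II"`, `"Pore-forming"`,
#'   `"Cytoplasmic"`, `"Extracellular"` or `"unannotated"`) and `pore_loop`
#'   (logical).
#' @export
locate <- function(topology, position) {
  mem <- topology[!topology$region %in% c("cytoplasmic", "extracellular"), ]
  topo <- topology[topology$region %in% c("cytoplasmic", "extracellular"), ]
  roman <- c(DI = "I", DII = "II", DIII = "III", DIV = "IV")

  s5 <- mem[mem$segment == "S5", ]
  s6 <- mem[mem$segment == "S6", ]
  loop <- dplyr::inner_join(
    s5[c("region", "end")], s6[c("region", "start")], by = "region")

  one <- function(pos) {
    hit <- mem[mem$start <= pos & pos <= mem$end, ]
    in_loop <- any(loop$end < pos & pos < loop$start)
    if (nrow(hit) == 1L) {
      lab <- if (hit$segment == "pore") "Pore-forming" else
        paste("Helical repeat", roman[[hit$region]])
      return(tibble::tibble(position = pos, domain = hit$region,
                            segment = hit$segment, label = lab,
                            pore_loop = in_loop || hit$segment == "pore"))
    }
    thit <- topo[topo$start <= pos & pos <= topo$end, ]
    lab <- if (nrow(thit) >= 1L) {
      c(cytoplasmic = "Cytoplasmic",
        extracellular = "Extracellular")[[thit$region[1]]]
    } else "unannotated"
    tibble::tibble(position = pos, domain = NA_character_,
                   segment = NA_character_, label = lab, pore_loop = in_loop)
  }
  dplyr::bind_rows(lapply(position, one))
}

#' Read a cohort variant table
#'
#' Reads a TSV with columns `individual_id`, `hgvs_p`, `var_class`,
#' `phenotype_group` and optionally `functional_evidence`, parses missense
#' (and nonsense) protein labels, derives broad classes and, when a
#' topology is supplied, maps missense positions onto it.
#'
#' @param file Path to the TSV file.
#' @param topology Optional [`protein_topology`][read_topology].
#' @return A tibble with the input columns plus `broad_class`, `position`
#'   and (with a topology) `domain`, `segment`, `location`, `pore_loop`.
#' @export
read_variants <- function(file, topology = NULL) {
  df <- readr::read_tsv(file, show_col_types = FALSE, comment = "#")
  need <- c("individual_id", "hgvs_p", "var_class", "phenotype_group")
  if (!all(need %in% names(df))) {
    stop("variant table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df$broad_class <- broad_class(df$var_class)
  # frameshift/splice records have no meaningful protein position
  locatable <- df$var_class %in% c("missense", "nonsense", "in-frame deletion") &
    !is.na(df$hgvs_p) & startsWith(df$hgvs_p, "p.")
  df$position <- NA_integer_
  if (any(locatable)) {
    df$position[locatable] <-
      parse_protein_variant(df$hgvs_p[locatable])$position
  }
  if (!is.null(topology)) {
    loc <- locate(topology, df$position[!is.na(df$position)])
    df$domain <- df$segment <- df$location <- NA_character_
    df$pore_loop <- NA
    df$domain[!is.na(df$position)] <- loc$domain
    df$segment[!is.na(df$position)] <- loc$segment
    df$location[!is.na(df$position)] <- loc$label
    df$pore_loop[!is.na(df$position)] <- loc$pore_loop
  }
  tibble::as_tibble(df)
}

#' Attach functional (GoF/LoF) labels to variant records
#'
#' Protein-truncating variants are loss-of-function unconditionally.
#' Missense variants are looked up in the functional-evidence table; those
#' absent from it, and variants with mixed gain- and loss-of-function
#' effects (evidence `"mixed"`), are `unclassified` and excluded from
#' function-based analyses.
#'
#' @param variants A variant tibble from [read_variants()] (needs columns
#'   `hgvs_p`, `broad_class`).
#' @param evidence A data frame with columns `hgvs_p` and `functional`
#'   (`"GoF"`, `"LoF"` or `"mixed"`). Contradictory rows for one variant are
#'   an error.
#' @return `variants` with a `functional` column over
#'   `GoF`/`LoF`/`unclassified`.
#' @export
assign_function <- function(variants, evidence) {
  if (!"broad_class" %in% names(variants)) {
    variants$broad_class <- broad_class(variants$var_class)
  }
  ev <- dplyr::distinct(tibble::as_tibble(evidence),
                        .data$hgvs_p, .data$functional)
  dup <- ev$hgvs_p[duplicated(ev$hgvs_p)]
  if (length(dup)) {
    stop("contradictory functional evidence for: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(ev$functional), c("GoF", "LoF", "mixed"))
  if (length(bad)) stop("invalid functional evidence value(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  out <- variants |>
    dplyr::left_join(ev, by = "hgvs_p") |>
    dplyr::mutate(functional = dplyr::case_when(
      .data$broad_class == "PTV" ~ "LoF",
      .data$functional %in% c("GoF", "LoF") & .data$broad_class == "missense" ~
        .data$functional,
      TRUE ~ "unclassified"
    ))
  out
}

#' Path to the bundled synthetic Na_V_1.2 topology table
#'
#' The intervals are a synthetic best-effort reconstruction of the Na_V_1.2
#' (SCN2A, 2005 aa) architecture: four homologous domains of six
#' transmembrane helices each, with an intramembrane pore-forming feature
#' between S5 and S6, and cytoplasmic/extracellular stretches elsewhere.
#' Boundaries are plausible, not measured; see [read_topology()].
#'
#' @return Path to a TSV file.
#' @export
nav12_topology_path <- function() {
  system.file("extdata", "nav12_topology_synthetic.tsv", package = "deepheno",
              mustWork = TRUE)
}

#' Path to the bundled 30-term mini phenotype ontology
#'
#' A hand-written OBO fixture with neurology-flavored term names, a single
#' root and a few diamond (multi-parent) structures, used in examples and
#' tests.
#'
#' @return Path to an OBO file.
#' @export
mini_hpo_path <- function() {
  system.file("extdata", "mini_hpo.obo", package = "deepheno", mustWork = TRUE)
}
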