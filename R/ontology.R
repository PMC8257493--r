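#' Parse an OBO flat file into a phenotype ontology DAG
#'
#' Reads an OBO 1.2/1.4 flat file and builds a rooted directed acyclic graph
#' of phenotype terms. Only the `id`, `name`, `alt_id`, `is_a` and
#' `is_obsolete` tags are interpreted; logical definitions, `part_of`
#' relations and cross-ontology axioms are ignored.
#'
#' Obsolete terms are retained in the term table (so stale annotations can be
#' reported) but carry no edges and are excluded from closure queries.
#' Alternate identifiers are mapped to their canonical term.
#'
#' @param file Path to an OBO file, or a character vector of OBO lines.
#' @param phenotype_root Term to restrict the graph to (the term and its
#'   descendants, plus its ancestors up to the ontology root). The default,
#'   `"HP:0000118"` (Phenotypic abnormality), is applied only when that term
#'   is present, so toy ontologies parse unrestricted. Use `NULL` to disable.
#' @return An object of class `ontology`: a list with elements `terms`
#'   (a tibble with columns `term`, `name`, `obsolete`), `parents` and
#'   `children` (named lists of character vectors), `ancestors` (named list
#'   of ancestor closures, each including the term itself), `alt` (named
#'   character vector mapping alternate to canonical ids) and `root`.
#' @examples
#' obo <- c("[Term]", "id: HP:0000001", "name: All",
#'          "[Term]", "id: HP:0000118", "name: Phenotypic abnormality",
#'          "is_a: HP:0000001 ! All")
#' onto <- parse_obo(obo)
#' onto$root
#' @export
parse_obo <- function(file, phenotype_root = "HP:0000118") {
  lines <- if (length(file) == 1L && !grepl("\n", file) && file.exists(file)) {
    readr::read_lines(file)
  } else {
    unlist(strsplit(file, "\n", fixed = TRUE))
  }

  stanza_starts <- which(lines == "[Term]")
  if (length(stanza_starts) == 0L) {
    stop("no [Term] stanzas found in OBO input", call. = FALSE)
  }
  bounds <- c(stanza_starts, length(lines) + 1L)
  other_stanzas <- grep("^\\[", lines)

  ids <- character(0)
  names_ <- character(0)
  obsolete <- logical(0)
  parents <- list()
  alt_from <- character(0)
  alt_to <- character(0)

  for (i in seq_along(stanza_starts)) {
    block <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    stop_at <- which(grepl("^\\[", block))[1]
    if (!is.na(stop_at)) block <- block[seq_len(stop_at - 1L)]
    tagval <- function(tag) {
      v <- block[startsWith(block, paste0(tag, ": "))]
      sub("\\s*!.*$", "", substring(v, nchar(tag) + 3L))
    }
    id <- tagval("id")[1]
    if (is.na(id)) next
    ids <- c(ids, id)
    nm <- tagval("name")[1]
    names_ <- c(names_, if (is.na(nm)) id else nm)
    obsolete <- c(obsolete, identical(tagval("is_obsolete")[1], "true"))
    parents[[id]] <- tagval("is_a")
    alts <- tagval("alt_id")
    if (length(alts)) {
      alt_from <- c(alt_from, alts)
      alt_to <- c(alt_to, rep(id, length(alts)))
    }
  }

  if (anyDuplicated(ids)) {
    stop("duplicate term ids in OBO input: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  names(obsolete) <- ids

  # obsolete terms carry no edges
  parents[ids[obsolete]] <- list(character(0))
  live <- ids[!obsolete]
  dangling <- setdiff(unique(unlist(parents)), ids)
  if (length(dangling)) {
    stop("is_a references unknown term(s): ",
         paste(dangling, collapse = ", "), call. = FALSE)
  }
  stale <- intersect(unique(unlist(parents)), ids[obsolete])
  if (length(stale)) {
    stop("is_a references obsolete term(s): ",
         paste(stale, collapse = ", "), call. = FALSE)
  }

  onto <- build_ontology(
    terms = tibble::tibble(term = ids, name = names_, obsolete = unname(obsolete)),
    parents = parents,
    alt = stats::setNames(alt_to, alt_from)
  )

  if (!is.null(phenotype_root) && phenotype_root %in% live) {
    keep <- union(descendant_closure(onto, phenotype_root),
                  onto$ancestors[[phenotype_root]])
    onto <- restrict_ontology(onto, keep)
  }
  onto
}

# Assemble + validate the DAG: cycle check (Kahn), single-root check,
# ancestor closures precomputed in topological order.
build_ontology <- function(terms, parents, alt = character(0)) {
  live <- terms$term[!terms$obsolete]
  parents <- parents[terms$term]
  names(parents) <- terms$term

  children <- stats::setNames(vector("list", length(terms$term)), terms$term)
  for (t in live) {
    for (p in parents[[t]]) children[[p]] <- c(children[[p]], t)
  }
  children <- lapply(children, function(x) if (is.null(x)) character(0) else x)

  # Kahn topological order over live terms; leftovers expose a cycle
  indeg <- vapply(parents[live], length, integer(1))
  order <- character(0)
  queue <- live[indeg == 0L]
  indeg_left <- indeg
  while (length(queue)) {
    t <- queue[1]; queue <- queue[-1]
    order <- c(order, t)
    for (ch in children[[t]]) {
      indeg_left[ch] <- indeg_left[ch] - 1L
      if (indeg_left[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order) < length(live)) {
    cyc <- find_cycle(parents, setdiff(live, order))
    stop("cyclic is_a relations detected: ",
         paste(cyc, collapse = " -> "), call. = FALSE)
  }

  roots <- live[vapply(parents[live], length, integer(1)) == 0L]
  if (length(roots) == 0L) stop("ontology has no root term", call. = FALSE)

  ancestors <- stats::setNames(vector("list", length(live)), live)
  for (t in order) {
    ps <- parents[[t]]
    ancestors[[t]] <- unique(c(t, unlist(ancestors[ps], use.names = FALSE)))
  }

  structure(
    list(terms = terms, parents = parents, children = children,
         ancestors = ancestors, alt = alt,
         root = if (length(roots) == 1L) roots else roots[order(roots)]),
    class = "ontology"
  )
}

# walk parent pointers from a node known to sit on/above a cycle
find_cycle <- function(parents, nodes) {
  t <- nodes[1]
  path <- t
  repeat {
    nxt <- intersect(parents[[t]], nodes)[1]
    if (nxt %in% path) {
      return(c(path[which(path == nxt)[1]:length(path)], nxt))
    }
    path <- c(path, nxt)
    t <- nxt
  }
}

restrict_ontology <- function(onto, keep) {
  keep_live <- intersect(names(onto$ancestors), keep)
  terms <- onto$terms[onto$terms$term %in% c(keep_live, onto$terms$term[onto$terms$obsolete]), ]
  parents <- lapply(onto$parents[terms$term], intersect, keep_live)
  alt <- onto$alt[onto$alt %in% keep_live]
  build_ontology(terms, parents, alt)
}

#' @export
print.ontology <- function(x, ...) {
  cat("<ontology> ", sum(!x$terms$obsolete), " terms (",
      sum(x$terms$obsolete), " obsolete), root: ",
      paste(x$root, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @method as_tibble ontology
#' @export
as_tibble.ontology <- function(x, ...) x$terms

#' Resolve term ids against an ontology
#'
#' Maps alternate ids to canonical ids (with a message reporting how many
#' were rewritten) and reports unknown ids.
#'
#' @param onto An [`ontology`][parse_obo].
#' @param terms Character vector of term ids.
#' @param on_unknown `"error"` (default) or `"na"` to return `NA` for ids
#'   that resolve to nothing.
#' @return Character vector of canonical ids, same length as `terms`.
#' @export
resolve_terms <- function(onto, terms, on_unknown = c("error", "na")) {
  on_unknown <- match.arg(on_unknown)
  out <- terms
  is_alt <- terms %in% names(onto$alt)
  if (any(is_alt)) {
    out[is_alt] <- unname(onto$alt[terms[is_alt]])
    message(sum(is_alt), " annotation(s) used alternate ids; canonicalized")
  }
  unknown <- !(out %in% names(onto$ancestors))
  if (any(unknown)) {
    if (on_unknown == "error") {
      stop("unknown term id(s): ", paste(unique(out[unknown]), collapse = ", "),
           call. = FALSE)
    }
    out[unknown] <- NA_character_
  }
  out
}

#' Ancestor closure of a set of terms
#'
#' Returns the union, over the input terms, of each term and all of its
#' ancestors up to the root. The closure includes the query terms themselves,
#' the standard convention for Resnik-type similarity (a term subsuming
#' another is a valid common ancestor).
#'
#' @param onto An [`ontology`][parse_obo].
#' @param terms Character vector of term ids (may be empty).
#' @return Character vector of term ids (unsorted, unique).
#' @export
ancestor_closure <- function(onto, terms) {
  if (length(terms) == 0L) return(character(0))
  check_known(onto, terms)
  unique(unlist(onto$ancestors[terms], use.names = FALSE))
}

#' Descendant closure of one or more terms
#'
#' Returns the union of each query term and all of its descendants.
#'
#' @inheritParams ancestor_closure
#' @param terms Character vector of term ids.
#' @return Character vector of term ids (unsorted, unique).
#' @export
descendant_closure <- function(onto, terms) {
  if (length(terms) == 0L) return(character(0))
  check_known(onto, terms)
  seen <- character(0)
  queue <- unique(terms)
  while (length(queue)) {
    t <- queue[1]; queue <- queue[-1]
    if (t %in% seen) next
    seen <- c(seen, t)
    queue <- c(queue, setdiff(onto$children[[t]], seen))
  }
  seen
}

check_known <- function(onto, terms) {
  unknown <- setdiff(terms, names(onto$ancestors))
  if (length(unknown)) {
    stop("unknown term id(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Term frequency and information content table
#'
#' Counts, for every term, the number of distinct individuals annotated with
#' it, and derives the cohort frequency `f = count / n` and the information
#' content `ic = -log2(f)` in bits. A term carried by every individual has
#' IC 0; a singleton term in a cohort of 413 has the maximal IC
#' `-log2(1/413) ~ 8.69` bits.
#'
#' @param annotations A data frame with columns `individual_id` and `term`
#'   (one row per annotation; duplicates are collapsed by set semantics).
#' @param n Cohort size. Defaults to the number of distinct individuals in
#'   `annotations`; pass it explicitly when the cohort includes individuals
#'   with no annotations.
#' @return A tibble with columns `term`, `count`, `f`, `ic`, sorted by
#'   decreasing count.
#' @export
term_frequencies <- function(annotations, n = NULL) {
  if (is.null(n)) n <- dplyr::n_distinct(annotations$individual_id)
  if (!is.numeric(n) || n < 1) stop("cohort size n must be >= 1", call. = FALSE)
  annotations |>
    dplyr::distinct(.data$individual_id, .data$term) |>
    dplyr::count(.data$term, name = "count") |>
    dplyr::mutate(f = .data$count / n, ic = -log2(.data$f)) |>
    dplyr::arrange(dplyr::desc(.data$count), .data$term)
}

#' Most informative common ancestor (MICA) of two terms
#'
#' Finds the common ancestor of `t1` and `t2` with maximal information
#' content under `freqs`. Each term counts among its own ancestors, so when
#' one term subsumes the other the subsumer is its own MICA. Ties are broken
#' by the lexicographically smallest term id, which leaves the IC value
#' unaffected.
#'
#' @inheritParams ancestor_closure
#' @param freqs A frequency table from [term_frequencies()] computed on the
#'   propagated dataset; every common ancestor of the query pair must be
#'   present (a missing term is an error, not a fallback).
#' @param t1,t2 Term ids.
#' @return A list with elements `term` and `ic`.
#' @export
mica <- function(onto, freqs, t1, t2) {
  check_known(onto, c(t1, t2))
  common <- intersect(onto$ancestors[[t1]], onto$ancestors[[t2]])
  if (length(common) == 0L) return(list(term = NA_character_, ic = 0))
  ic <- freqs$ic[match(common, freqs$term)]
  if (anyNA(ic)) {
    stop("term(s) missing from frequency table: ",
         paste(common[is.na(ic)], collapse = ", "),
         "; supply complete propagated frequencies", call. = FALSE)
  }
  best <- ic == max(ic)
  winner <- min(common[best])
  list(term = winner, ic = max(ic))
}

# Pairwise MICA IC lookup for a set of terms. Fills the matrix from the
# highest-IC ancestor downward: the first ancestor shared by a pair wins.
mica_ic_matrix <- function(onto, freqs, terms) {
  check_known(onto, terms)
  anc_sets <- onto$ancestors[terms]
  anc_all <- unique(unlist(anc_sets, use.names = FALSE))
  ic <- freqs$ic[match(anc_all, freqs$term)]
  if (anyNA(ic)) {
    stop("term(s) missing from frequency table: ",
         paste(anc_all[is.na(ic)], collapse = ", "), call. = FALSE)
  }
  names(ic) <- anc_all
  m <- length(terms)
  out <- matrix(0, m, m, dimnames = list(terms, terms))
  filled <- matrix(FALSE, m, m)
  # ancestor indicator: term x ancestor
  for (a in anc_all[order(ic, decreasing = TRUE)]) {
    if (all(filled)) break
    if (ic[[a]] <= 0) break  # remaining pairs share only IC-0 ancestors
    desc <- which(vapply(anc_sets, function(s) a %in% s, logical(1)))
    if (length(desc) < 1L) next
    blk <- filled[desc, desc, drop = FALSE]
    if (all(blk)) next
    sub <- out[desc, desc, drop = FALSE]
    sub[!blk] <- ic[[a]]
    out[desc, desc] <- sub
    filled[desc, desc] <- TRUE
  }
  out
}

#' Write an ontology to an OBO flat file
#'
#' Emits `[Term]` stanzas with `id`, `name`, `is_a` and `is_obsolete` tags,
#' sufficient to round-trip any ontology built or parsed by this package.
#'
#' @param onto An [`ontology`][parse_obo].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_obo <- function(onto, file) {
  stanza <- function(t) {
    nm <- onto$terms$name[onto$terms$term == t]
    obs <- onto$terms$obsolete[onto$terms$term == t]
    ps <- onto$parents[[t]]
    c("", "[Term]", paste0("id: ", t), paste0("name: ", nm),
      if (length(ps)) paste0("is_a: ", ps),
      if (obs) "is_obsolete: true")
  }
  lines <- c("format-version: 1.2",
             unlist(lapply(onto$terms$term, stanza)))
  writeLines(lines, file)
  invisible(file)
}
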