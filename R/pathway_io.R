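#' Construct a pathway collection
#'
#' A pathway is described by the set of metabolite identifiers annotated to
#' it. Collections preserve source-file order, which matters for the greedy
#' non-redundant construction ([build_nonredundant_set()]).
#'
#' @param sets named list of character vectors; names are unique pathway ids,
#'   elements are non-empty metabolite identifier sets.
#' @param names optional named character vector of display names (defaults to
#'   the pathway ids).
#' @param source provenance tag, one of `"reactome"`, `"kegg"`, `"gmt"`,
#'   `"synthetic"`.
#' @param species species string, if applicable.
#' @return An object of class `PathwayCollection`.
#' @export
pathway_collection <- function(sets, names = NULL,
                               source = c("gmt", "reactome", "kegg", "synthetic"),
                               species = NA_character_) {
  source <- match.arg(source)
  if (!is.list(sets) || is.null(base::names(sets)))
    stopf("`sets` must be a named list of identifier vectors")
  ids <- base::names(sets)
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stopf("duplicate pathway id(s): %s", paste(head(dup, 5), collapse = ", "))
  }
  sets <- lapply(sets, function(s) unique(normalize_metabolite_ids(s)))
  empty <- vapply(sets, function(s) length(s) == 0L, logical(1))
  if (any(empty))
    stopf("empty member set(s) for pathway(s): %s",
          paste(head(ids[empty], 5), collapse = ", "))
  if (is.null(names)) names <- setNames(ids, ids)
  names <- setNames(as.character(names[ids] %||% ids), ids)
  names[is.na(names)] <- ids[is.na(names)]
  structure(list(sets = sets, names = names, source = source, species = species),
            class = "PathwayCollection")
}

#' @export
length.PathwayCollection <- function(x) length(x$sets)

#' @export
`[.PathwayCollection` <- function(x, i) {
  ids <- names(x$sets)[seq_along(x$sets)]
  if (is.character(i)) i <- match(i, names(x$sets))
  pathway_collection(x$sets[i], names = x$names[names(x$sets)[i]],
                     source = x$source, species = x$species)
}

#' @export
print.PathwayCollection <- function(x, ...) {
  sizes <- lengths(x$sets)
  cat(sprintf("PathwayCollection (%s): %d pathways, member sizes %d-%d\n",
              x$source, length(x$sets),
              if (length(sizes)) min(sizes) else 0L,
              if (length(sizes)) max(sizes) else 0L))
  invisible(x)
}

#' @rdname pathway_collection
#' @param x a `PathwayCollection`.
#' @export
pathway_ids <- function(x) names(x$sets)

#' @rdname pathway_collection
#' @export
pathway_sets <- function(x) x$sets

# Trim whitespace and normalise the ChEBI prefix to upper case. No
# cross-database identifier mapping is attempted.
normalize_metabolite_ids <- function(x) {
  x <- trimws(as.character(x))
  sub("^[Cc][Hh][Ee][Bb][Ii]:", "CHEBI:", x)
}

#' Parse a GMT file into a pathway collection
#'
#' Standard gene-set GMT format reused for metabolite sets: one pathway per
#' line, tab-separated `id<TAB>description<TAB>member1<TAB>member2...`.
#' Duplicate member identifiers within a line are collapsed.
#'
#' @param path path to the GMT file.
#' @param source source tag to record, `"gmt"` by default.
#' @return A [pathway_collection()].
#' @export
parse_gmt <- function(path, source = "gmt") {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stopf("empty GMT file: %s", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stopf("malformed GMT line %d: fewer than 3 tab-separated fields",
          which(nf < 3L)[1L])
  ids <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(ids))
    stopf("duplicate pathway id(s) in GMT: %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  descs <- vapply(fields, `[[`, character(1), 2L)
  sets <- lapply(fields, function(f) {
    mem <- f[-(1:2)]
    mem[nzchar(trimws(mem))]
  })
  names(sets) <- ids
  pathway_collection(sets, names = setNames(descs, ids), source = source)
}

#' Write a pathway collection to a GMT file
#' @param collection a `PathwayCollection`.
#' @param path output path.
#' @export
write_gmt <- function(collection, path) {
  ids <- pathway_ids(collection)
  lines <- vapply(ids, function(id) {
    paste(c(id, collection$names[[id]], collection$sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Parse the Reactome ChEBI flat file
#'
#' Reads the `ChEBI2Reactome_All_Levels.txt` tab-separated format (ChEBI id,
#' pathway stable id, URL, pathway name, evidence code, species), restricted
#' to an exact species match. Member identifiers are normalised to
#' `CHEBI:<digits>` form and pathway order follows first appearance in the
#' file.
#'
#' @param path path to the flat file.
#' @param species species string to keep, e.g. `"Homo sapiens"`.
#' @return A [pathway_collection()].
#' @export
parse_reactome_chebi <- function(path, species = "Homo sapiens") {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- read.delim(path, header = FALSE, sep = "\t", quote = "",
                   stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(df) < 6L) stopf("expected >= 6 tab-separated columns, got %d", ncol(df))
  keep <- df[[6L]] == species
  if (!any(keep))
    stopf("no rows for species '%s'; species present: %s", species,
          paste(sort(unique(df[[6L]])), collapse = ", "))
  df <- df[keep, , drop = FALSE]
  member <- ifelse(grepl("^[Cc][Hh][Ee][Bb][Ii]:", trimws(df[[1L]])),
                   trimws(df[[1L]]), paste0("CHEBI:", trimws(df[[1L]])))
  pid <- df[[2L]]
  # preserve first-appearance order of pathway ids
  ord <- unique(pid)
  sets <- split(member, factor(pid, levels = ord))
  pnames <- df[[4L]][!duplicated(pid)]
  names(pnames) <- ord
  pathway_collection(as.list(sets), names = pnames, source = "reactome",
                     species = species)
}

#' Restrict a collection to pathways with sufficient measured coverage
#'
#' Intersects every pathway's member set with the metabolites measured in
#' `matrix` and keeps pathways with at least `min_coverage` measured members.
#' Member sets in the returned collection are the measured subsets (all
#' scoring operates on measured members only); full definition sizes are
#' reported in the attached coverage table.
#'
#' @param collection a `PathwayCollection`.
#' @param matrix a `MetaboliteMatrix` (or numeric matrix with metabolite
#'   column names).
#' @param min_coverage minimum number of measured members, default 2.
#' @return The filtered `PathwayCollection`, with a `data.frame` of per-pathway
#'   coverage (columns `pathway_id`, `full_size`, `coverage`) attached as
#'   attribute `"coverage"`; retrieve it with [coverage_report()].
#' @export
filter_by_coverage <- function(collection, matrix, min_coverage = 2) {
  if (min_coverage < 1) stopf("`min_coverage` must be >= 1")
  measured <- metabolite_ids(matrix)
  sub <- lapply(collection$sets, function(s) s[s %in% measured])
  cov <- lengths(sub)
  keep <- cov >= min_coverage
  if (!any(keep))
    stopf(paste0("no pathway has >= %d measured members; check that matrix ",
                 "column names and pathway members use the same identifier ",
                 "namespace"), min_coverage)
  out <- pathway_collection(sub[keep],
                            names = collection$names[names(collection$sets)[keep]],
                            source = collection$source,
                            species = collection$species)
  report <- data.frame(pathway_id = names(collection$sets)[keep],
                       full_size = lengths(collection$sets)[keep],
                       coverage = cov[keep],
                       row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "coverage") <- report
  out
}

#' @rdname filter_by_coverage
#' @export
coverage_report <- function(collection) attr(collection, "coverage")

#' Szymkiewicz-Simpson overlap coefficient
#'
#' `OC(A, B) = |A intersect B| / min(|A|, |B|)`. Zero when the sets are
#' disjoint; one whenever the smaller set is contained in the larger.
#'
#' @param A,B non-empty character vectors of identifiers (treated as sets).
#' @return A number in `[0, 1]`.
#' @examples
#' overlap_coefficient(c("a", "b"), c("a", "b", "c", "d", "e")) # 1
#' @export
overlap_coefficient <- function(A, B) {
  A <- unique(A); B <- unique(B)
  if (length(A) == 0L || length(B) == 0L)
    stopf("overlap coefficient undefined for empty sets")
  length(intersect(A, B)) / min(length(A), length(B))
}

#' Greedy construction of a non-redundant pathway set
#'
#' Scans pathways in their original collection order and accepts a pathway
#' only if its member set shares no identifiers with the union of all
#' previously accepted pathways' members. Every pair in the result therefore
#' has overlap coefficient zero.
#'
#' @param collection a `PathwayCollection` (order preserved from source).
#' @return A `PathwayCollection` containing the accepted pathways in
#'   acceptance order.
#' @export
build_nonredundant_set <- function(collection) {
  if (!length(collection$sets)) stopf("empty pathway collection")
  accepted <- character(0)
  M <- character(0)
  for (id in names(collection$sets)) {
    s <- collection$sets[[id]]
    if (!any(s %in% M)) {
      accepted <- c(accepted, id)
      M <- c(M, s)
    }
  }
  pathway_collection(collection$sets[accepted],
                     names = collection$names[accepted],
                     source = collection$source, species = collection$species)
}
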