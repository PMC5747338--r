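#' Create a gene set
#'
#' A gene set is a named, ordered collection of unique gene identifiers with
#' free-text description and optional annotation fields (database ID, URL,
#' PubMed ID, contributor, ...).
#'
#' @param name Set name, unique within a collection.
#' @param description Free-text description (may be empty).
#' @param members Character vector of gene IDs; duplicates are removed keeping
#'   the first occurrence.
#' @param annotation Named list of annotation strings.
#' @param id Stable identifier; defaults to `name`.
#' @return An object of class `gene_set`.
#' @export
gene_set <- function(name, description = "", members, annotation = list(),
                     id = name) {
  members <- as.character(members)
  members <- members[!duplicated(members)]
  if (length(members) == 0L)
    stop("gene set '", name, "' has no members")
  structure(
    list(id = as.character(id), name = as.character(name),
         description = as.character(description), members = members,
         annotation = annotation),
    class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat("ID:", x$id, "\n")
  cat("GeneSet:", x$name, "\n")
  cat("Description:", x$description, "\n")
  for (key in names(x$annotation))
    cat(paste0(key, ":"), as.character(x$annotation[[key]]), "\n")
  cat("NumGenes:", length(x$members), "\n")
  invisible(x)
}

#' Read a GMT gene set collection
#'
#' Parses the tab-delimited GMT dialect: one set per line with fields
#' name, description, then one or more member gene IDs. Member duplicates are
#' dropped keeping first occurrence; the description may be empty; members are
#' tokenised on tabs only.
#'
#' @param path Path to a GMT file.
#' @return List of [gene_set()] objects (empty list for an empty file).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L)
      stop("malformed GMT line ", i, " in ", path,
           ": expected at least 3 tab-separated fields, got ", length(fields))
    sets[[i]] <- gene_set(name = fields[[1]], description = fields[[2]],
                          members = fields[-(1:2)])
  }
  nm <- vapply(sets, `[[`, character(1), "name")
  if (anyDuplicated(nm))
    stop("duplicate gene set name(s) in ", path, ": ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  names(sets) <- nm
  sets
}

#' Write a GMT gene set collection
#'
#' Inverse of [read_gmt()]: tab-separated, newline-terminated, one set per
#' line. `read_gmt(write_gmt(x, f))` reproduces `x`'s names, descriptions and
#' members exactly.
#'
#' @param sets List of [gene_set()] objects.
#' @param path Output file path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s) {
    paste(c(s$name, s$description, s$members), collapse = "\t")
  }, character(1))
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(lines)) writeLines(lines, con)
  invisible(path)
}

#' Resolve gene sets against an expression gene universe
#'
#' Maps every set member to its row position in the supplied gene universe
#' (the rownames of the expression matrix). Members absent from the universe
#' are dropped; sets left with fewer than `min_size` resolved members are
#' excluded. Each retained set records its resolved/original member counts
#' (the "23/24" semantics of collection summaries).
#'
#' @param sets List of [gene_set()] objects.
#' @param universe Character vector of unique gene IDs in expression-row
#'   order.
#' @param min_size Minimum number of resolved members for a set to be kept.
#'   Small sets destabilise several base statistics; default 5.
#' @param name,label,version,date,species Collection metadata strings.
#' @return A `collection_index`: list with `sets` (retained gene sets),
#'   `index` (per-set integer row positions, 1-based), `n_original`,
#'   `n_resolved`, `universe_size` and the metadata fields.
#' @export
build_index <- function(sets, universe, min_size = 5,
                        name = "Custom collection", label = "custom",
                        version = "NA", date = format(Sys.Date()),
                        species = "unknown") {
  universe <- as.character(universe)
  if (length(universe) == 0L) stop("empty gene universe")
  if (anyDuplicated(universe))
    stop("duplicate IDs in gene universe: ",
         paste(utils::head(unique(universe[duplicated(universe)]), 5),
               collapse = ", "))
  idx <- lapply(sets, function(s) {
    i <- match(s$members, universe)
    i[!is.na(i)]
  })
  names(idx) <- vapply(sets, `[[`, character(1), "name")
  n_orig <- vapply(sets, function(s) length(s$members), integer(1))
  n_res <- lengths(idx)
  keep <- n_res >= min_size
  sets <- sets[keep]
  names(sets) <- vapply(sets, `[[`, character(1), "name")
  structure(
    list(sets = sets, index = idx[keep],
         n_original = n_orig[keep], n_resolved = as.integer(n_res[keep]),
         universe_size = length(universe), universe = universe,
         min_size = min_size, name = name, label = label,
         version = version, date = date, species = species),
    class = "collection_index")
}

#' Number of gene sets in an indexed collection
#' @param ci A `collection_index`.
#' @export
n_sets <- function(ci) length(ci$sets)

#' Look up a gene set by name
#'
#' Exact, case-sensitive lookup in an indexed collection.
#'
#' @param ci A `collection_index`.
#' @param name Set name.
#' @return The [gene_set()] with an added `NumGenes` annotation
#'   ("resolved/original").
#' @export
get_set_by_name <- function(ci, name) {
  pos <- match(name, names(ci$sets))
  if (is.na(pos))
    stop("gene set '", name, "' not found in collection '", ci$label, "'")
  s <- ci$sets[[pos]]
  s$annotation$NumGenes <- paste0(ci$n_resolved[[pos]], "/",
                                  ci$n_original[[pos]])
  s
}

#' One-line summary of an indexed collection
#'
#' @param ci A `collection_index`.
#' @return A string
#'   `"<name> (<label>): <n> gene sets - Version: <v>, Update date: <d>"`.
#' @export
summarize_collection <- function(ci) {
  sprintf("%s (%s): %d gene sets - Version: %s, Update date: %s",
          ci$name, ci$label, n_sets(ci), ci$version, ci$date)
}

#' @export
print.collection_index <- function(x, ...) {
  cat("Indexed gene set collection\n")
  cat(summarize_collection(x), "\n")
  cat("Total number of indexing genes:", x$universe_size, "\n")
  cat("Species:", x$species, "\n")
  invisible(x)
}

#' Read a feature-to-symbol map
#'
#' Two-column tab-separated file with header `FeatureID<TAB>Symbols`, used to
#' show gene symbols instead of raw feature IDs in reports.
#'
#' @param path TSV path.
#' @return Named character vector mapping feature ID to symbol.
#' @export
read_symbols_map <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  if (ncol(df) < 2L) stop("symbols map needs two columns: ", path)
  stats::setNames(df[[2]], df[[1]])
}
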