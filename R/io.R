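# Readers and writers for the package's tabular formats plus the
# Braun-Blanquet cover conversion. Delimited files are UTF-8 with a header
# row; tab vs comma is auto-detected from the header line; decimal point '.'.

#' Names of the seven climate variables expected in plot metadata
#'
#' Mean annual temperature, mean January temperature, mean August
#' temperature, mean growing-season (May-August) temperature, August-January
#' temperature difference, mean annual precipitation and mean growing-season
#' precipitation.
#'
#' @return character vector of column names.
#' @export
climate_vars <- function() {
  c("t_ann", "t_jan", "t_aug", "t_grow", "t_diff", "p_ann", "p_grow")
}

# internal: sniff the field separator from the header line
detect_sep <- function(path) {
  header <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("\t", header)) "\t" else ","
}

read_table_auto <- function(path) {
  sep <- detect_sep(path)
  read.delim(path, sep = sep, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Read a rooted phylogeny from a Newick file
#'
#' Parses with [ape::read.tree()] and enforces the invariants the rest of the
#' package relies on: at least two uniquely-labelled tips, branch lengths
#' present on every edge and non-negative.
#'
#' @param path path to a Newick file.
#' @return an [ape::phylo] object.
#' @export
read_newick <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("failed to parse Newick file: ", path)
  validate_phylogeny(tree)
}

#' @rdname read_newick
#' @param tree an [ape::phylo] object to validate in place.
#' @export
validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (ape::Ntip(tree) < 2) stop("phylogeny must have at least 2 tips")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels in phylogeny: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  if (any(!nzchar(tree$tip.label))) stop("empty tip label in phylogeny")
  if (is.null(tree$edge.length)) stop("phylogeny has no branch lengths")
  if (anyNA(tree$edge.length) ||
      length(tree$edge.length) != nrow(tree$edge))
    stop("phylogeny has missing branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length in phylogeny")
  tree
}

#' Read a plots-by-species community matrix
#'
#' First column holds plot identifiers; remaining columns are species
#' abundances (any non-negative cover unit). Every plot must contain at
#' least one positive entry.
#'
#' @param path delimited file path.
#' @return numeric matrix, plots in rows, species in columns.
#' @export
read_community <- function(path) {
  df <- read_table_auto(path)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  validate_community(m)
}

#' @rdname read_community
#' @param m plots-by-species numeric matrix to validate.
#' @export
validate_community <- function(m) {
  if (anyDuplicated(rownames(m))) stop("duplicate plot ids")
  if (anyDuplicated(colnames(m))) stop("duplicate species ids")
  if (anyNA(m)) stop("missing abundance values")
  if (any(m < 0)) stop("negative abundance in community matrix")
  if (any(rowSums(m) == 0)) {
    bad <- rownames(m)[rowSums(m) == 0]
    stop("plot(s) with no positive abundance: ", paste(bad, collapse = ", "))
  }
  m
}

#' Read a species-by-trait table
#'
#' Expects one row per species with the five canonical woody-plant traits:
#' `max_height` (m), `leaf_length` (cm), `leaf_width` (cm), `flowering_onset`
#' (month, 1-12), `seed_mass` (mg). Extra columns are preserved but ignored
#' by the analyses. All trait values must be strictly positive so that the
#' log transform is defined.
#'
#' @param path delimited file path; first column = species id.
#' @return data.frame with rownames = species ids.
#' @export
read_traits <- function(path) {
  df <- read_table_auto(path)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stop("duplicate species ids in trait table")
  out <- df[, -1, drop = FALSE]
  rownames(out) <- ids
  tr <- intersect(trait_vars(), names(out))
  if (length(tr) == 0) stop("no recognised trait columns found")
  vals <- as.matrix(out[, tr])
  if (anyNA(vals)) stop("missing trait values")
  if (any(vals <= 0))
    stop("trait values must be strictly positive (log-transformable)")
  fo <- out[["flowering_onset"]]
  if (!is.null(fo) && any(fo < 1 | fo > 12))
    stop("flowering_onset must lie in 1..12")
  out
}

#' Canonical trait column names
#' @return character vector.
#' @export
trait_vars <- function() {
  c("max_height", "leaf_length", "leaf_width", "flowering_onset", "seed_mass")
}

#' Read plot metadata
#'
#' One row per plot with transect id, elevation (m), latitude/longitude
#' (decimal degrees), slope (degrees), rocky-area ratio `rar` (fraction of
#' line-intercept segments on rock, in `[0, 1]`) and the seven climate
#' variables of [climate_vars()].
#'
#' @param path delimited file path; first column = plot id.
#' @return data.frame with a `plot_id` column.
#' @export
read_metadata <- function(path) {
  df <- read_table_auto(path)
  names(df)[1] <- "plot_id"
  df$plot_id <- as.character(df$plot_id)
  validate_metadata(df)
}

#' @rdname read_metadata
#' @param df metadata data.frame to validate.
#' @export
validate_metadata <- function(df) {
  need <- c("plot_id", "transect_id", "elevation", "latitude", "longitude",
            "slope", "rar", climate_vars())
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("metadata missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$plot_id)) stop("duplicate plot ids in metadata")
  if (any(df$rar < 0 | df$rar > 1)) stop("rar outside [0, 1]")
  if (any(abs(df$latitude) > 90)) stop("latitude outside [-90, 90]")
  if (any(abs(df$longitude) > 180)) stop("longitude outside [-180, 180]")
  df
}

#' Convert Braun-Blanquet cover-abundance codes to percent cover midpoints
#'
#' The ordinal field scale (r, +, 1, 2, 3, 4, 5) is mapped to the midpoint
#' of each cover class under the standard ordinal-midpoint convention:
#' r = 0.1, + = 0.5, 1 = 2.5 (midpoint of 0-5%), 2 = 15 (5-25%),
#' 3 = 37.5 (25-50%), 4 = 62.5 (50-75%), 5 = 87.5 (75-100%). The mapping is
#' a convention, not a measurement, and can be overridden.
#'
#' @param code character vector of Braun-Blanquet codes.
#' @param table named numeric vector giving the midpoint for each code;
#'   override to use a different convention.
#' @return numeric vector of percent covers.
#' @export
#' @examples
#' bb_to_cover(c("r", "+", "1", "5"))
bb_to_cover <- function(code, table = bb_midpoints()) {
  code <- as.character(code)
  unknown <- setdiff(unique(code), names(table))
  if (length(unknown))
    stop("unknown Braun-Blanquet code(s): ",
         paste(unknown, collapse = ", "),
         "; accepted codes: ", paste(names(table), collapse = ", "))
  unname(table[code])
}

#' @rdname bb_to_cover
#' @export
bb_midpoints <- function() {
  c("r" = 0.1, "+" = 0.5, "1" = 2.5, "2" = 15,
    "3" = 37.5, "4" = 62.5, "5" = 87.5)
}

#' Write a table or tree in the package's exchange formats
#'
#' Tables go out tab-separated with a header row (and rownames as a first
#' `id` column when present); trees as Newick via [ape::write.tree()].
#'
#' @param x matrix/data.frame or `phylo` object.
#' @param path output path.
#' @param id_col name for the first column when rownames are written.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path, id_col = "id") {
  if (inherits(x, "phylo")) {
    ape::write.tree(x, file = path)
    return(invisible(path))
  }
  x <- as.data.frame(x, check.names = FALSE)
  if (!is.null(attr(x, "row.names")) &&
      !identical(attr(x, "row.names"), seq_len(nrow(x)))) {
    x <- cbind(setNames(data.frame(rownames(x), stringsAsFactors = FALSE),
                        id_col), x)
  }
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Match a community matrix against a tree and trait table
#'
#' Species present in the community but absent from the phylogeny or trait
#' table are a hard error by default; with `drop_unmatched = TRUE` they are
#' removed with a message (plots left empty after dropping are an error).
#'
#' @param comm plots-by-species matrix.
#' @param tree optional `phylo`.
#' @param traits optional trait data.frame (rownames = species).
#' @param drop_unmatched drop (with a message) instead of erroring.
#' @return the (possibly reduced) community matrix.
#' @export
match_species <- function(comm, tree = NULL, traits = NULL,
                          drop_unmatched = FALSE) {
  known <- colnames(comm)
  if (!is.null(tree)) known <- intersect(known, tree$tip.label)
  if (!is.null(traits)) known <- intersect(known, rownames(traits))
  bad <- setdiff(colnames(comm), known)
  if (length(bad)) {
    if (!drop_unmatched)
      stop("species missing from tree/trait table: ",
           paste(bad, collapse = ", "))
    message("dropping ", length(bad), " unmatched species: ",
            paste(bad, collapse = ", "))
    comm <- comm[, known, drop = FALSE]
    if (any(rowSums(comm) == 0))
      stop("plot(s) left empty after dropping unmatched species")
  }
  comm
}
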