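#' Construct a bipartite mutualistic network
#'
#' A bipartite network records which animal (pollinator) interacts with which
#' plant as a binary incidence matrix with `A` rows (animals) and `P` columns
#' (plants). All downstream matrices index species animals-first: species
#' `1..A` are animals, `A+1..A+P` are plants.
#'
#' @param incidence Numeric or integer matrix of 0/1 entries, animals in rows,
#'   plants in columns. Values greater than zero (e.g. visit counts) are
#'   accepted only when `coerce = TRUE`, in which case they are binarized with
#'   a warning.
#' @param animal_labels,plant_labels Optional character vectors of species
#'   labels; defaults are `"A1".."A<A>"` and `"P1".."P<P>"`.
#' @param coerce Binarize positive entries instead of failing on non-binary
#'   cells.
#' @param relax Allow isolated species (all-zero rows/columns). Off by
#'   default: a species with no partners has an undefined degree-scaled
#'   interaction weight.
#'
#' @return An object of class `bipartite_network`: a list with elements
#'   `incidence` (labelled integer matrix), `animal_labels`, `plant_labels`.
#' @examples
#' net <- bipartite_network(matrix(c(1, 1, 1, 0), 2, 2, byrow = TRUE))
#' network_summary(net)
#' @export
bipartite_network <- function(incidence, animal_labels = NULL,
                              plant_labels = NULL, coerce = FALSE,
                              relax = FALSE) {
  if (!is.matrix(incidence)) incidence <- as.matrix(incidence)
  if (length(incidence) == 0L || nrow(incidence) < 1L || ncol(incidence) < 1L) {
    abort("incidence matrix must have at least one row and one column")
  }
  mode(incidence) <- "numeric"
  if (anyNA(incidence)) abort("incidence matrix contains missing values")
  if (any(incidence < 0)) abort("incidence matrix contains negative entries")
  nonbinary <- incidence != 0 & incidence != 1
  if (any(nonbinary)) {
    if (!coerce) {
      abort("incidence matrix has non-binary entries; set coerce = TRUE to binarize")
    }
    warn(sprintf("binarizing %d non-binary incidence entries at > 0", sum(nonbinary)))
    incidence <- (incidence > 0) + 0
  }
  A <- nrow(incidence)
  P <- ncol(incidence)
  animal_labels <- animal_labels %||% rownames(incidence) %||% paste0("A", seq_len(A))
  plant_labels <- plant_labels %||% colnames(incidence) %||% paste0("P", seq_len(P))
  if (length(animal_labels) != A) abort("animal_labels length must equal nrow(incidence)")
  if (length(plant_labels) != P) abort("plant_labels length must equal ncol(incidence)")
  if (anyDuplicated(c(animal_labels, plant_labels))) {
    abort("species labels must be unique across animals and plants")
  }
  storage.mode(incidence) <- "integer"
  dimnames(incidence) <- list(animal_labels, plant_labels)
  if (!relax && (any(rowSums(incidence) == 0L) || any(colSums(incidence) == 0L))) {
    abort("isolated species (zero-degree row or column); set relax = TRUE to allow")
  }
  structure(
    list(incidence = incidence,
         animal_labels = as.character(animal_labels),
         plant_labels = as.character(plant_labels)),
    class = "bipartite_network"
  )
}

#' @export
print.bipartite_network <- function(x, ...) {
  s <- network_summary(x)
  cat(sprintf(
    "<bipartite_network> %d animals x %d plants, %d links (connectance %.4f)\n",
    s$A, s$P, s$L, s$C
  ))
  invisible(x)
}

#' @rdname network_summary
#' @export
species_labels <- function(net) {
  stopifnot(inherits(net, "bipartite_network"))
  c(net$animal_labels, net$plant_labels)
}

#' Per-species degrees, animals first
#'
#' @param net A [bipartite_network()].
#' @return Named integer vector of length `S = A + P`.
#' @export
degrees <- function(net) {
  stopifnot(inherits(net, "bipartite_network"))
  k <- c(rowSums(net$incidence), colSums(net$incidence))
  setNames(as.integer(k), species_labels(net))
}

#' Topological summary of a bipartite network
#'
#' Connectance follows the unipartite convention `C = L / (S (S - 1))`, the
#' fraction of realized links among all ordered species pairs, so that values
#' are comparable across networks of different guild balance.
#'
#' @param net A [bipartite_network()].
#' @return One-row tibble with species counts `S`, `A`, `P`, link count `L`,
#'   connectance `C`, and the degree vector `k` as a list column.
#' @examples
#' net <- bipartite_network(matrix(c(1, 1, 1, 0), 2, 2, byrow = TRUE))
#' network_summary(net)$C # 3 / (4 * 3)
#' @export
network_summary <- function(net) {
  stopifnot(inherits(net, "bipartite_network"))
  A <- nrow(net$incidence)
  P <- ncol(net$incidence)
  S <- A + P
  L <- sum(net$incidence)
  tibble(
    S = S, A = A, P = P, L = L,
    C = L / (S * (S - 1)),
    k = list(degrees(net))
  )
}

#' Symmetric species-by-species adjacency matrix
#'
#' Expands the `A x P` incidence into the `S x S` block form
#' `[[0, B], [B', 0]]` used to build interaction matrices; the within-guild
#' blocks are zero because mutualistic links only join animals to plants.
#'
#' @param net A [bipartite_network()].
#' @return Symmetric binary `S x S` matrix with zero diagonal, species
#'   ordered animals-first.
#' @export
as_adjacency <- function(net) {
  stopifnot(inherits(net, "bipartite_network"))
  B <- net$incidence
  A <- nrow(B)
  P <- ncol(B)
  S <- A + P
  adj <- matrix(0L, S, S, dimnames = list(species_labels(net), species_labels(net)))
  adj[seq_len(A), A + seq_len(P)] <- B
  adj[A + seq_len(P), seq_len(A)] <- t(B)
  adj
}

#' Convert to an igraph object
#'
#' @param net A [bipartite_network()].
#' @return An undirected `igraph` graph with a logical `type` vertex
#'   attribute (`TRUE` for plants), as igraph's bipartite convention expects.
#' @export
as_igraph <- function(net) {
  g <- igraph::graph_from_biadjacency_matrix(net$incidence)
  g
}

is_connected_net <- function(net) {
  igraph::is_connected(as_igraph(net))
}

#' Read and write incidence matrices
#'
#' The on-disk layout mirrors the interaction-web-database pollination
#' matrices: an optional header row of plant labels, a first column of animal
#' labels, and a body of 0/1 integers. The delimiter is taken from `dialect`
#' (`"tsv"` or `"csv"`), defaulting on file extension.
#'
#' @param path File path.
#' @param dialect `"tsv"` or `"csv"`; default guesses from the extension.
#' @param labeled Whether the file carries a label header row and label
#'   column; if `FALSE`, labels are generated.
#' @param coerce,relax Passed to [bipartite_network()].
#' @param largest_component Keep only the largest connected component
#'   (never applied silently; default `FALSE`).
#' @return `read_incidence()` returns a [bipartite_network()];
#'   `write_incidence()` invisibly returns `path`.
#' @export
read_incidence <- function(path, dialect = NULL, labeled = TRUE,
                           coerce = FALSE, relax = FALSE,
                           largest_component = FALSE) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  sep <- dialect_sep(dialect, path)
  if (labeled) {
    df <- utils::read.table(path, sep = sep, header = TRUE, row.names = 1,
                            check.names = FALSE, comment.char = "#")
    m <- as.matrix(df)
    net <- bipartite_network(m, animal_labels = rownames(m),
                             plant_labels = colnames(m),
                             coerce = coerce, relax = relax || largest_component)
  } else {
    m <- as.matrix(utils::read.table(path, sep = sep, header = FALSE,
                                     comment.char = "#"))
    dimnames(m) <- NULL
    net <- bipartite_network(m, coerce = coerce,
                             relax = relax || largest_component)
  }
  if (largest_component) net <- keep_largest_component(net, relax = relax)
  net
}

#' @rdname read_incidence
#' @param net A [bipartite_network()] to write.
#' @export
write_incidence <- function(net, path, dialect = NULL) {
  stopifnot(inherits(net, "bipartite_network"))
  sep <- dialect_sep(dialect, path)
  df <- as.data.frame(net$incidence)
  utils::write.table(df, path, sep = sep, quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}

dialect_sep <- function(dialect, path) {
  dialect <- dialect %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "tsv"
  switch(dialect, tsv = "\t", csv = ",",
         abort(sprintf("unknown dialect '%s' (use 'tsv' or 'csv')", dialect)))
}

keep_largest_component <- function(net, relax = FALSE) {
  g <- as_igraph(net)
  comp <- igraph::components(g)
  if (comp$no == 1L) return(net)
  keep <- comp$membership == which.max(comp$csize)
  A <- nrow(net$incidence)
  rows <- keep[seq_len(A)]
  cols <- keep[A + seq_len(ncol(net$incidence))]
  bipartite_network(net$incidence[rows, cols, drop = FALSE],
                    animal_labels = net$animal_labels[rows],
                    plant_labels = net$plant_labels[cols],
                    relax = relax)
}

#' Read and write edge lists
#'
#' Each non-comment line holds one interaction as
#' `animal_label<TAB>plant_label`. Duplicated pairs collapse to a single link
#' with a warning; a label may not appear on both sides. Label order follows
#' first appearance in the file.
#'
#' @param path File path; `'#'` lines are ignored.
#' @inheritParams read_incidence
#' @return `read_edge_list()` returns a [bipartite_network()];
#'   `write_edge_list()` invisibly returns `path`.
#' @export
read_edge_list <- function(path, coerce = FALSE, relax = FALSE) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) abort("edge list is empty")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad) > 0L) {
    abort(sprintf("line %d does not have exactly 2 tab-separated fields", bad[1]))
  }
  animals_col <- vapply(parts, `[[`, character(1), 1L)
  plants_col <- vapply(parts, `[[`, character(1), 2L)
  if (length(intersect(animals_col, plants_col)) > 0L) {
    abort(sprintf("label appears on both sides: %s",
                  intersect(animals_col, plants_col)[1]))
  }
  pairs <- paste(animals_col, plants_col, sep = "\r")
  if (anyDuplicated(pairs)) {
    warn(sprintf("%d duplicated edge(s) collapsed", sum(duplicated(pairs))))
  }
  a_lab <- unique(animals_col)
  p_lab <- unique(plants_col)
  m <- matrix(0L, length(a_lab), length(p_lab),
              dimnames = list(a_lab, p_lab))
  m[cbind(match(animals_col, a_lab), match(plants_col, p_lab))] <- 1L
  bipartite_network(m, animal_labels = a_lab, plant_labels = p_lab,
                    coerce = coerce, relax = relax)
}

#' @rdname read_edge_list
#' @param net A [bipartite_network()] to write.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "bipartite_network"))
  idx <- which(net$incidence == 1L, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  writeLines(paste(net$animal_labels[idx[, 1]],
                   net$plant_labels[idx[, 2]], sep = "\t"), path)
  invisible(path)
}

#' @export
tidy.bipartite_network <- function(x, ...) {
  k <- degrees(x)
  tibble(
    species = names(k),
    guild = rep(c("animal", "plant"),
                c(length(x$animal_labels), length(x$plant_labels))),
    degree = unname(k)
  )
}

#' @export
glance.bipartite_network <- function(x, ...) {
  s <- network_summary(x)
  dplyr::select(s, -"k")
}
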