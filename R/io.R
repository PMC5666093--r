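#' Read and validate a grouped-sighting dataset
#'
#' Reads the three input tables — grouped-sighting encounters, individual
#' registry, and annual resource-abundance series — from CSV (header row,
#' UTF-8, comma-separated) and cross-validates them. Period ids are kept as
#' strings so pooled periods such as `"1976-1977"` are first-class.
#'
#' Expected schemas:
#' * encounters: `period`, `encounter`, `group`, `individual`
#' * individuals: `id`, `sex` (`M`/`F`/`U`), `first_period`, `last_period`,
#'   `fate` (`died`/`censored`)
#' * salmon: `year`, `index` (non-negative; missing years are allowed and
#'   simply excluded from resource-stratified analyses)
#'
#' @param encounters_path,individuals_path,salmon_path CSV file paths.
#' @return List with validated `encounters`, `registry`, `salmon` data
#'   frames.
#' @export
read_dataset <- function(encounters_path, individuals_path, salmon_path) {
  enc <- read.csv(encounters_path, colClasses = "character",
                  fileEncoding = "UTF-8")
  reg <- read.csv(individuals_path, colClasses = "character",
                  fileEncoding = "UTF-8")
  sal_raw <- read.csv(salmon_path, colClasses = "character",
                      fileEncoding = "UTF-8")
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) stop_socsurv(what, " file lacks column(s): ",
                                   paste(miss, collapse = ", "))
  }
  need(enc, c("period", "encounter", "group", "individual"), "encounters")
  need(reg, c("id", "sex", "first_period", "last_period", "fate"),
       "individuals")
  need(sal_raw, c("year", "index"), "salmon")

  year <- suppressWarnings(as.integer(sal_raw$year))
  if (anyNA(year)) stop_socsurv("non-integer year in salmon file")
  idx <- suppressWarnings(as.numeric(sal_raw$index))
  bad <- is.na(idx) & !(is.na(sal_raw$index) | sal_raw$index %in% c("", "NA"))
  if (any(bad)) stop_socsurv("non-numeric salmon index: '",
                             sal_raw$index[bad][1L], "'")
  salmon <- data.frame(year = year, index = idx)
  validate_dataset(enc, reg, salmon)
  list(encounters = enc, registry = reg, salmon = salmon)
}

validate_dataset <- function(encounters, registry, salmon = NULL) {
  if (anyDuplicated(registry$id)) {
    stop_socsurv("duplicate individual id(s) in registry: ",
                 registry$id[duplicated(registry$id)][1L],
                 class = "socsurv_schema_error")
  }
  if (!all(registry$sex %in% c("M", "F", "U"))) {
    stop_socsurv("sex must be one of M, F, U",
                 class = "socsurv_schema_error")
  }
  if (!all(registry$fate %in% c("died", "censored"))) {
    stop_socsurv("fate must be 'died' or 'censored'",
                 class = "socsurv_schema_error")
  }
  stray <- setdiff(encounters$individual, registry$id)
  if (length(stray)) {
    stop_socsurv("encounter references individual(s) absent from the ",
                 "registry: ", paste(head(stray, 3L), collapse = ", "),
                 class = "socsurv_integrity_error")
  }
  dup <- duplicated(paste(encounters$encounter, encounters$individual,
                          sep = "\r"))
  if (any(dup)) {
    stop_socsurv("individual appears in more than one group of encounter ",
                 encounters$encounter[dup][1L],
                 class = "socsurv_integrity_error")
  }
  if (!is.null(salmon)) {
    if (anyDuplicated(salmon$year)) {
      stop_socsurv("duplicate year in salmon series",
                   class = "socsurv_schema_error")
    }
    if (any(salmon$index < 0, na.rm = TRUE)) {
      stop_socsurv("negative salmon index", class = "socsurv_schema_error")
    }
  }
  invisible(TRUE)
}

#' Write a dataset to CSV files
#'
#' Inverse of [read_dataset()]; writing then re-reading is the identity.
#' For a simulated dataset the ground truth is written alongside as JSON.
#'
#' @param data List with `encounters`, `registry`, `salmon`, and optionally
#'   `truth` (a `ground_truth`).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the file paths written.
#' @export
write_dataset <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("encounters.csv", "individuals.csv",
                            "salmon.csv"))
  write.csv(data$encounters, paths[1L], row.names = FALSE)
  write.csv(data$registry, paths[2L], row.names = FALSE)
  write.csv(data$salmon, paths[3L], row.names = FALSE)
  if (!is.null(data$truth)) {
    tp <- file.path(dir, "ground_truth.json")
    tr <- data$truth
    jsonlite::write_json(
      list(true_partition = as.list(tr$true_partition),
           hazard = tr$hazard,
           death_period = as.list(tr$death_period),
           true_sex = as.list(tr$true_sex),
           true_centrality = tr$true_centrality),
      tp, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
    paths <- c(paths, tp)
  }
  invisible(paths)
}

#' Export a period's network as GraphML (and optionally a CSV edge list)
#'
#' Writes the SRI-weighted network with node attributes (sex, community id,
#' centrality where available) and the SRI as edge attribute `sri` (also
#' stored as `weight`), in a form Gephi and igraph can re-open. A network
#' with no positive-weight dyads yields a valid file with zero edges.
#'
#' @param m An `sri_matrix`.
#' @param path Output GraphML path.
#' @param partition Optional `community_partition` over the same node set.
#' @param centrality Optional `centrality_table` for the period.
#' @param registry Optional registry supplying the `sex` attribute.
#' @param edge_csv Optional path for a CSV edge list
#'   (`node_a`, `node_b`, `sri`).
#' @return Invisibly, the igraph object written.
#' @export
write_network <- function(m, path, partition = NULL, centrality = NULL,
                          registry = NULL, edge_csv = NULL) {
  stopifnot(inherits(m, "sri_matrix"))
  g <- igraph::graph_from_adjacency_matrix(m$weights, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  if (length(igraph::E(g))) {
    igraph::E(g)$sri <- igraph::E(g)$weight
  }
  if (!is.null(partition)) {
    if (!setequal(names(partition$assignment), m$nodes)) {
      stop_socsurv("partition and matrix cover different node sets")
    }
    igraph::V(g)$community <- unname(partition$assignment[m$nodes])
  }
  if (!is.null(registry)) {
    igraph::V(g)$sex <- registry$sex[match(m$nodes, registry$id)]
  }
  if (!is.null(centrality)) {
    ix <- match(m$nodes, centrality$individual)
    igraph::V(g)$degree_norm <- centrality$degree_norm[ix]
    igraph::V(g)$closeness_rank_norm <- centrality$closeness_rank_norm[ix]
  }
  igraph::write_graph(g, path, format = "graphml")
  if (!is.null(edge_csv)) {
    el <- igraph::as_edgelist(g)
    write.csv(data.frame(node_a = el[, 1L], node_b = el[, 2L],
                         sri = if (nrow(el)) igraph::E(g)$weight else numeric(0)),
              edge_csv, row.names = FALSE)
  }
  invisible(g)
}

#' Read a GraphML network back as a weight matrix
#'
#' Round-trip companion of [write_network()].
#'
#' @param path GraphML file path.
#' @return List with `weights` (symmetric matrix) and `attributes` (data
#'   frame of node attributes).
#' @export
read_network <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  W <- igraph::as_adjacency_matrix(g, attr = if (length(igraph::E(g)))
    "weight" else NULL, sparse = FALSE)
  nm <- igraph::V(g)$name
  if (is.null(rownames(W)) && !is.null(nm)) dimnames(W) <- list(nm, nm)
  attrs <- as.data.frame(igraph::vertex_attr(g), stringsAsFactors = FALSE)
  list(weights = W, attributes = attrs)
}
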