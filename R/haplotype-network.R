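## Haplotype collapsing and minimum spanning networks.
##
## The minimum spanning network (MSN) on unique haplotypes contains every
## edge that belongs to at least one minimum spanning tree of the pairwise
## mutational-step distances; ties therefore appear as reticulations.

#' Collapse aligned sequences into unique haplotypes
#'
#' Sequences are uppercased and grouped by exact string equality, in order of
#' first occurrence. A sequence containing an ambiguity code never merges
#' with a resolved sequence; such haplotypes are flagged.
#'
#' @param sequences named character vector of aligned sequences (names =
#'   individual ids; ids of the form `<ind>_<island>` contribute island
#'   counts).
#' @param islands optional character vector of island labels per individual;
#'   if missing, parsed from ids as the text after the last underscore.
#' @return Object of class `haplotype_set`: list with `haplotypes` (data
#'   frame `hap_id`, `sequence`, `frequency`, `ambiguous`), `members` (list
#'   of ids per haplotype) and `island_counts` (haplotype x island matrix,
#'   when islands are available).
#' @export
collapse_haplotypes <- function(sequences, islands = NULL) {
  if (length(sequences) == 0L) stopf("no sequences supplied")
  if (is.null(names(sequences)))
    names(sequences) <- sprintf("seq%d", seq_along(sequences))
  seqs <- toupper(as.character(sequences))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    off <- names(sequences)[lens != stats::median(lens)]
    stopf("sequences are not aligned to equal length; offending id(s): %s",
          paste(off, collapse = ", "))
  }
  if (is.null(islands)) {
    has_us <- grepl("_", names(sequences))
    islands <- ifelse(has_us, sub("^.*_", "", names(sequences)), NA_character_)
  }
  first <- !duplicated(seqs)
  uniq <- seqs[first]
  hap_id <- sprintf("H%02d", seq_along(uniq))
  idx <- match(seqs, uniq)
  members <- split(names(sequences), factor(idx, levels = seq_along(uniq)))
  names(members) <- hap_id
  haplotypes <- data.frame(
    hap_id = hap_id, sequence = uniq,
    frequency = as.integer(tabulate(idx, length(uniq))),
    ambiguous = grepl("[^ACGT]", uniq), stringsAsFactors = FALSE)
  island_counts <- NULL
  if (!all(is.na(islands))) {
    island_counts <- table(factor(hap_id[idx], levels = hap_id), islands)
    island_counts <- unclass(as.matrix(island_counts))
    names(dimnames(island_counts)) <- NULL
  }
  structure(list(haplotypes = haplotypes, members = members,
                 island_counts = island_counts), class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat(sprintf("<haplotype_set> %d haplotypes from %d sequences (%d bp)\n",
              nrow(x$haplotypes), sum(x$haplotypes$frequency),
              nchar(x$haplotypes$sequence[1L])))
  invisible(x)
}

#' Pairwise mutational-step distances between haplotypes
#'
#' The number of sites at which both sequences carry an unambiguous A/C/G/T
#' base and the bases differ (pairwise deletion of ambiguous sites and gaps).
#'
#' @param hapset a [collapse_haplotypes()] result, or a character vector of
#'   equal-length sequences.
#' @return Symmetric integer matrix with zero diagonal.
#' @export
pairwise_differences <- function(hapset) {
  seqs <- if (inherits(hapset, "haplotype_set")) hapset$haplotypes$sequence
          else toupper(as.character(hapset))
  n <- length(seqs)
  if (n < 1L) stopf("need at least one haplotype")
  chars <- strsplit(seqs, "", fixed = TRUE)
  L <- lengths(chars)
  if (length(unique(L)) != 1L) stopf("sequences must have equal length")
  mat <- do.call(rbind, chars)
  ok <- mat == "A" | mat == "C" | mat == "G" | mat == "T"
  d <- matrix(0L, n, n)
  if (n >= 2L) {
    for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
      use <- ok[i, ] & ok[j, ]
      d[i, j] <- d[j, i] <- sum(mat[i, use] != mat[j, use])
    }
  }
  nm <- if (inherits(hapset, "haplotype_set")) hapset$haplotypes$hap_id
        else names(seqs) %||% sprintf("H%02d", seq_len(n))
  dimnames(d) <- list(nm, nm)
  d
}

#' Minimum spanning network from a distance matrix
#'
#' An edge (i, j) is included iff its weight equals the minimax path weight
#' between i and j, i.e. iff it belongs to at least one minimum spanning tree
#' (union over all MSTs; the tie tolerance epsilon is 0).
#'
#' @param d symmetric non-negative distance matrix; off-diagonal zeros are
#'   rejected (haplotypes must be unique).
#' @param hapset optional [collapse_haplotypes()] result carried along for
#'   reporting.
#' @return Object of class `haplotype_network`: list with `edges` (data
#'   frame `from`, `to`, `steps`), `n_nodes`, `node_ids`, `hapset`.
#' @export
minimum_spanning_network <- function(d, hapset = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 1L || ncol(d) != n) stopf("distance matrix must be square")
  if (any(d < 0)) stopf("distances must be non-negative")
  if (any(abs(d - t(d)) > 1e-9)) stopf("distance matrix must be symmetric")
  if (n >= 2L) {
    offdiag <- d[upper.tri(d)]
    if (any(offdiag == 0))
      stopf("zero distance between distinct haplotypes; collapse them first")
  }
  ids <- rownames(d) %||% sprintf("H%02d", seq_len(n))
  if (n == 1L) {
    return(structure(list(edges = data.frame(from = character(0),
                                             to = character(0),
                                             steps = numeric(0)),
                          n_nodes = 1L, node_ids = ids, hapset = hapset),
                     class = "haplotype_network"))
  }
  ## minimax path weights via a Floyd-Warshall style relaxation on max
  mm <- d
  for (k in seq_len(n))
    mm <- pmin(mm, outer(mm[, k], mm[k, ], pmax))
  keep <- which(upper.tri(d) & d <= mm + 1e-12, arr.ind = TRUE)
  edges <- data.frame(from = ids[keep[, 1L]], to = ids[keep[, 2L]],
                      steps = d[keep], stringsAsFactors = FALSE)
  edges <- edges[order(edges$steps, edges$from, edges$to), ]
  rownames(edges) <- NULL
  structure(list(edges = edges, n_nodes = n, node_ids = ids,
                 hapset = hapset), class = "haplotype_network")
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat(sprintf("<haplotype_network> %d haplotypes, %d edges, total weight %g\n",
              x$n_nodes, nrow(x$edges), sum(x$edges$steps)))
  invisible(x)
}

#' Build the haplotype network from raw sequences
#'
#' Collapse, distance and MSN in one call.
#'
#' @param sequences named character vector of aligned sequences.
#' @param islands optional island labels, see [collapse_haplotypes()].
#' @return A `haplotype_network` whose `hapset` holds frequencies and island
#'   counts.
#' @export
build_haplotype_network <- function(sequences, islands = NULL) {
  hs <- collapse_haplotypes(sequences, islands)
  minimum_spanning_network(pairwise_differences(hs), hapset = hs)
}

#' Write network files
#'
#' Writes a TSV edge list (`hap_i`, `hap_j`, `steps`), a node table CSV with
#' frequencies and island counts, and a GraphML file.
#'
#' @param network a `haplotype_network`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return Invisibly, the paths written.
#' @export
write_network_files <- function(network, dir, prefix = "haplotype_network") {
  stopifnot(inherits(network, "haplotype_network"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p_edges <- file.path(dir, paste0(prefix, "_edges.tsv"))
  ed <- network$edges
  names(ed) <- c("hap_i", "hap_j", "steps")
  utils::write.table(ed, p_edges, sep = "\t", quote = FALSE, row.names = FALSE)
  p_nodes <- file.path(dir, paste0(prefix, "_nodes.csv"))
  nodes <- data.frame(hap_id = network$node_ids, stringsAsFactors = FALSE)
  if (!is.null(network$hapset)) {
    nodes$frequency <- network$hapset$haplotypes$frequency
    ic <- network$hapset$island_counts
    if (!is.null(ic)) nodes <- cbind(nodes, as.data.frame(ic))
  }
  utils::write.csv(nodes, p_nodes, row.names = FALSE)
  g <- igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                     vertices = nodes)
  p_graphml <- file.path(dir, paste0(prefix, ".graphml"))
  igraph::write_graph(g, p_graphml, format = "graphml")
  invisible(c(edges = p_edges, nodes = p_nodes, graphml = p_graphml))
}
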