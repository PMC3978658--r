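#' Filter AP-MS peptide evidence
#'
#' Applies the inclusion rule that a protein is only considered identified
#' in a purification when supported by at least `min_peptides` peptides
#' (default 2).
#'
#' @param evidence data.frame with columns `bait`, `protein`,
#'   `peptides` (non-negative integer).
#' @param min_peptides Minimum peptide count (default 2).
#' @return The filtered evidence data.frame.
#' @export
filter_evidence <- function(evidence, min_peptides = 2L) {
  stopifnot(all(c("bait", "protein", "peptides") %in% names(evidence)))
  if (any(evidence$peptides < 0))
    stop_spec("negative peptide counts")
  evidence[evidence$peptides >= min_peptides, , drop = FALSE]
}

#' Build the bait x protein copurification matrix
#'
#' Duplicate (bait, protein) rows are aggregated (summed peptide counts)
#' with a warning before binarisation. Columns are limited to proteins that
#' passed the peptide filter in at least one purification.
#'
#' @param filtered Filtered evidence from [filter_evidence()].
#' @param all_proteins Optional character vector fixing the column order.
#' @return A logical matrix (rows = baits, columns = proteins) of class
#'   `copurification_matrix`.
#' @export
build_matrix <- function(filtered, all_proteins = NULL) {
  baits <- unique(filtered$bait)
  if (length(baits) == 0L) stop_spec("no baits in the evidence table")
  key <- paste(filtered$bait, filtered$protein, sep = "\r")
  if (anyDuplicated(key)) {
    warning("aggregating duplicate (bait, protein) evidence rows")
    agg <- stats::aggregate(peptides ~ bait + protein, data = filtered,
                            FUN = sum)
    filtered <- agg
  }
  proteins <- if (is.null(all_proteins)) {
    sort(unique(filtered$protein))
  } else all_proteins
  m <- matrix(FALSE, length(baits), length(proteins),
              dimnames = list(baits, proteins))
  m[cbind(match(filtered$bait, baits),
          match(filtered$protein, proteins))] <- TRUE
  class(m) <- c("copurification_matrix", class(m))
  m
}

#' Deduce subcomplexes from a copurification matrix
#'
#' Bait proteins are joined by an edge when their detection is reciprocal:
#' each partner's purification detects the other. Connected components of
#' this reciprocal-detection graph are the candidate subcomplexes. Each
#' component is then refined so that every member of a group of size >= 2
#' has support (the fraction of the group's bait purifications detecting
#' it) at least `support_threshold`: the weakest-supported member is removed
#' and re-grouped among the removed set until the group is coherent. This
#' makes single spurious reciprocal detections (false-positive cells in
#' both directions) unable to fuse two otherwise coherent subcomplexes.
#' Prey-only proteins (never used as bait) attach to the group detecting
#' them in at least `support_threshold` of its bait purifications, or stay
#' singletons.
#'
#' An optional contaminant filter first drops proteins present in more than
#' `contaminant_fraction` of all purifications, a proxy for "not apparently
#' specific" background proteins.
#'
#' @param matrix A `copurification_matrix` from [build_matrix()].
#' @param support_threshold Minimum within-group detection fraction
#'   (default 0.75).
#' @param contaminant_fraction Optional fraction in `(0, 1]`; proteins
#'   detected in more than this fraction of purifications are dropped
#'   before deduction (default `NULL`, no filter).
#' @return A `subcomplex_call` data.frame: `protein`, `group` (integer id,
#'   groups numbered by size then name), `support`.
#' @export
deduce_subcomplexes <- function(matrix, support_threshold = 0.75,
                                contaminant_fraction = NULL) {
  stopifnot(is.matrix(matrix), nrow(matrix) >= 1)
  m <- matrix
  if (!is.null(contaminant_fraction)) {
    freq <- colMeans(m)
    keep <- freq <= contaminant_fraction | colnames(m) %in% rownames(m)
    m <- m[, keep, drop = FALSE]
  }
  baits <- rownames(m)
  proteins <- colnames(m)
  # reciprocal-detection graph over baits
  bait_cols <- match(baits, proteins)
  adj <- matrix(FALSE, length(baits), length(baits),
                dimnames = list(baits, baits))
  for (i in seq_along(baits)) {
    for (j in seq_along(baits)) {
      if (i == j) next
      ij <- !is.na(bait_cols[j]) && m[i, bait_cols[j]]
      ji <- !is.na(bait_cols[i]) && m[j, bait_cols[i]]
      adj[i, j] <- ij && ji
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  groups <- split(names(comp), comp)
  groups <- unlist(lapply(groups, refine_group, m = m, bait_cols = bait_cols,
                          threshold = support_threshold, proteins = proteins),
                   recursive = FALSE)
  # attach prey-only proteins
  prey_only <- setdiff(proteins, baits)
  attach_support <- function(p, members) {
    bs <- intersect(members, baits)
    if (length(bs) == 0L) return(0)
    mean(m[bs, p])
  }
  for (p in prey_only) {
    sup <- vapply(groups, attach_support, numeric(1), p = p)
    if (length(sup) > 0 && max(sup) >= support_threshold) {
      k <- which.max(sup)
      groups[[k]] <- c(groups[[k]], p)
    } else {
      groups[[length(groups) + 1L]] <- p
    }
  }
  # deterministic ordering: by decreasing size, then first member name
  ord <- order(-vapply(groups, length, integer(1)),
               vapply(groups, function(g) sort(g)[1], character(1)))
  groups <- groups[ord]
  out <- NULL
  for (k in seq_along(groups)) {
    members <- sort(groups[[k]])
    bs <- intersect(groups[[k]], baits)
    sup <- vapply(members, function(p) {
      if (length(bs) == 0L || !p %in% proteins) return(1)
      mean(m[bs, p])
    }, numeric(1))
    out <- rbind(out, data.frame(protein = members, group = k,
                                 support = unname(sup),
                                 stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  class(out) <- c("subcomplex_call", "data.frame")
  out
}

# enforce the support invariant within one component: repeatedly remove the
# weakest-supported member and re-group the removed members among themselves
refine_group <- function(members, m, bait_cols, threshold, proteins) {
  if (length(members) <= 1L) return(list(members))
  current <- members
  removed <- character(0)
  repeat {
    if (length(current) <= 1L) break
    cols <- match(current, proteins)
    sup <- vapply(cols, function(cc) {
      if (is.na(cc)) 0 else mean(m[current, cc])
    }, numeric(1))
    if (all(sup >= threshold)) break
    worst <- current[which.min(sup)]
    removed <- c(removed, worst)
    current <- setdiff(current, worst)
  }
  out <- list(current)
  if (length(removed) > 0) {
    # re-run reciprocal grouping among the removed baits
    sub <- lapply(split_reciprocal(removed, m, proteins), identity)
    out <- c(out, unlist(lapply(sub, refine_group, m = m,
                                bait_cols = bait_cols,
                                threshold = threshold,
                                proteins = proteins),
                         recursive = FALSE))
  }
  out
}

split_reciprocal <- function(baits_sub, m, proteins) {
  if (length(baits_sub) == 1L) return(list(baits_sub))
  adj <- matrix(FALSE, length(baits_sub), length(baits_sub),
                dimnames = list(baits_sub, baits_sub))
  cols <- match(baits_sub, proteins)
  for (i in seq_along(baits_sub)) {
    for (j in seq_along(baits_sub)) {
      if (i == j) next
      adj[i, j] <- (!is.na(cols[j]) && m[baits_sub[i], cols[j]]) &&
        (!is.na(cols[i]) && m[baits_sub[j], cols[i]])
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  unname(split(names(comp), comp))
}

#' @export
print.subcomplex_call <- function(x, ...) {
  for (k in unique(x$group)) {
    members <- x$protein[x$group == k]
    cat(sprintf("group %d (%d): %s\n", k, length(members),
                paste(members, collapse = ", ")))
  }
  invisible(x)
}

#' Read and write AP-MS tables
#'
#' Evidence tables are TSV with columns `bait`, `protein`, `peptides`;
#' subcomplex calls are written as two columns (`protein`, `group`) plus
#' the support score.
#'
#' @param path TSV path.
#' @return For `read_evidence_tsv`, the evidence data.frame.
#' @export
read_evidence_tsv <- function(path) {
  ev <- read_tsv(path)
  stopifnot(all(c("bait", "protein", "peptides") %in% names(ev)))
  ev
}

#' @rdname read_evidence_tsv
#' @param calls A `subcomplex_call` data.frame.
#' @export
write_subcomplexes_tsv <- function(calls, path) {
  write_tsv(as.data.frame(calls), path)
  invisible(path)
}

#' Noise-free kinetochore copurification fixture
#'
#' Encodes the reciprocal copurification pattern of the three deduced
#' kinetochore subcomplexes (KKT14-KKT15; KKT16-KKT17-KKT18;
#' KKT6-KKT7-KKT8-KKT9-KKT10-KKT11-KKT12-KKT19) as a block-diagonal
#' bait x protein evidence table in which every bait detects every member
#' of its own subcomplex with `peptides_within` peptides.
#'
#' @param peptides_within Peptide count for true within-complex detections
#'   (default 5).
#' @return An evidence data.frame (`bait`, `protein`, `peptides`).
#' @export
kkt_subcomplex_fixture <- function(peptides_within = 5L) {
  blocks <- kkt_subcomplex_membership()
  ev <- NULL
  for (b in blocks) {
    ev <- rbind(ev, expand.grid(bait = b, protein = b,
                                stringsAsFactors = FALSE))
  }
  ev$peptides <- peptides_within
  ev
}

#' @rdname kkt_subcomplex_fixture
#' @export
kkt_subcomplex_membership <- function() {
  list(c("KKT14", "KKT15"),
       c("KKT16", "KKT17", "KKT18"),
       c("KKT6", "KKT7", "KKT8", "KKT9", "KKT10", "KKT11", "KKT12",
         "KKT19"))
}
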