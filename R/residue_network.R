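#' @title Residue interaction networks and betweenness profiles
#' @description Builds an interaction-strength graph over protein
#'   residues from a PDB structure and computes the normalized
#'   betweenness centrality profile used to post-process predicted driver
#'   positions: for residue i, the sum over residue pairs (j, k) of the
#'   fraction of shortest paths between j and k passing through i,
#'   normalized by (N-1)(N-2)/2 within i's connected component.
#' @name residue_network
NULL

#' Build a residue interaction graph from a PDB structure
#'
#' Heavy-atom contacts within `cutoff` angstroms define the raw contact
#' count n_ij between residues i and j; the interaction strength is
#' normalized as I_ij = 100 * n_ij / sqrt(N_i * N_j), where N_i is the
#' total number of heavy-atom contacts residue i makes in the structure.
#' An edge is retained when I_ij exceeds `i_min` percent. Sequence-adjacent
#' residues are excluded by default so that backbone-dominated contacts do
#' not produce trivial edges.
#'
#' @param pdb path to a PDB file, or a `bio3d` pdb object.
#' @param i_min interaction-strength threshold in percent (default 4).
#' @param cutoff heavy-atom contact distance cutoff in angstroms
#'   (default 4.5).
#' @param exclude_adjacent drop edges between residues adjacent in
#'   sequence on the same chain (default TRUE).
#' @return an object of class `residue_graph`: `nodes` (data.frame:
#'   `node` id string "chain:resno[ins]", `chain`, `resno`, `resid`) and
#'   `edges` (data.frame: `i`, `j` node indices with i < j, `weight` =
#'   I_ij).
#' @export
build_graph <- function(pdb, i_min = 4, cutoff = 4.5,
                        exclude_adjacent = TRUE) {
  if (is.character(pdb)) {
    if (!file.exists(pdb)) stop("PDB file not found: ", pdb)
    pdb <- bio3d::read.pdb(pdb, verbose = FALSE)
  }
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("no protein atoms in structure")
  # heavy atoms only; first altloc kept
  elty <- toupper(trimws(at$elety))
  hyd <- grepl("^[0-9]*H", elty)
  at <- at[!hyd, , drop = FALSE]
  alt <- trimws(ifelse(is.na(at$alt), "", at$alt))
  at <- at[alt %in% c("", "A"), , drop = FALSE]
  if (nrow(at) == 0L) stop("no heavy atoms in structure")
  ins <- trimws(ifelse(is.na(at$insert), "", at$insert))
  res_id <- paste0(at$chain, ":", at$resno, ins)
  nodes_first <- !duplicated(res_id)
  nodes <- data.frame(node = res_id[nodes_first], chain = at$chain[nodes_first],
                      resno = at$resno[nodes_first],
                      resid = at$resid[nodes_first], stringsAsFactors = FALSE)
  if (nrow(nodes) < 2L) stop("structure must contain at least 2 residues")
  ridx <- match(res_id, nodes$node)
  xyz <- cbind(at$x, at$y, at$z)
  # all heavy-atom pairs within cutoff (structures here are small; the
  # dense distance matrix is fine)
  D <- as.matrix(stats::dist(xyz))
  within <- which(D <= cutoff & upper.tri(D), arr.ind = TRUE)
  ri <- ridx[within[, 1]]; rj <- ridx[within[, 2]]
  inter <- ri != rj
  ri <- ri[inter]; rj <- rj[inter]
  lo <- pmin(ri, rj); hi <- pmax(ri, rj)
  if (length(lo) == 0L) {
    return(structure(list(nodes = nodes,
                          edges = data.frame(i = integer(0), j = integer(0),
                                             weight = numeric(0)),
                          i_min = i_min, cutoff = cutoff),
                     class = "residue_graph"))
  }
  key <- paste(lo, hi)
  tab <- base::table(key)
  n_ij <- as.numeric(tab)
  pair <- do.call(rbind, strsplit(names(tab), " "))
  pi <- as.integer(pair[, 1]); pj <- as.integer(pair[, 2])
  # total contacts per residue (before any exclusion)
  N_i <- stats::setNames(rep(0, nrow(nodes)), seq_len(nrow(nodes)))
  for (r in seq_along(pi)) {
    N_i[pi[r]] <- N_i[pi[r]] + n_ij[r]
    N_i[pj[r]] <- N_i[pj[r]] + n_ij[r]
  }
  I_ij <- 100 * n_ij / sqrt(N_i[pi] * N_i[pj])
  keep <- I_ij > i_min
  if (exclude_adjacent) {
    adj <- nodes$chain[pi] == nodes$chain[pj] &
      abs(nodes$resno[pi] - nodes$resno[pj]) == 1L
    keep <- keep & !adj
  }
  structure(
    list(nodes = nodes,
         edges = data.frame(i = pi[keep], j = pj[keep], weight = I_ij[keep]),
         i_min = i_min, cutoff = cutoff),
    class = "residue_graph"
  )
}

#' @export
print.residue_graph <- function(x, ...) {
  cat(sprintf("Residue interaction graph: %d residues, %d edges (I_min %g%%, cutoff %g A)\n",
              nrow(x$nodes), nrow(x$edges), x$i_min, x$cutoff))
  invisible(x)
}

#' Construct a residue graph directly from nodes and edges
#'
#' For synthetic graphs in analyses and tests.
#' @param n_nodes number of nodes (named `r1..rn`, chain A).
#' @param edges two-column matrix/data.frame of node index pairs; an
#'   optional third column gives weights (default 1).
#' @return a `residue_graph`.
#' @export
residue_graph_from_edges <- function(n_nodes, edges) {
  edges <- as.data.frame(edges)
  w <- if (ncol(edges) >= 3L) as.numeric(edges[[3]]) else rep(1, nrow(edges))
  i <- pmin(edges[[1]], edges[[2]]); j <- pmax(edges[[1]], edges[[2]])
  structure(
    list(nodes = data.frame(node = paste0("A:", seq_len(n_nodes)),
                            chain = "A", resno = seq_len(n_nodes),
                            resid = "GLY", stringsAsFactors = FALSE),
         edges = data.frame(i = i, j = j, weight = w)[!duplicated(paste(i, j)) &
                                                        i != j, , drop = FALSE],
         i_min = 0, cutoff = NA_real_),
    class = "residue_graph"
  )
}

adjacency_list <- function(graph) {
  n <- nrow(graph$nodes)
  adj <- vector("list", n)
  for (v in seq_len(n)) adj[[v]] <- list(nbr = integer(0), w = numeric(0))
  for (r in seq_len(nrow(graph$edges))) {
    i <- graph$edges$i[r]; j <- graph$edges$j[r]; w <- graph$edges$weight[r]
    adj[[i]]$nbr <- c(adj[[i]]$nbr, j); adj[[i]]$w <- c(adj[[i]]$w, w)
    adj[[j]]$nbr <- c(adj[[j]]$nbr, i); adj[[j]]$w <- c(adj[[j]]$w, w)
  }
  adj
}

connected_components <- function(graph) {
  n <- nrow(graph$nodes)
  adj <- adjacency_list(graph)
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s; comp[s] <- cid
    while (length(queue) > 0L) {
      v <- queue[1]; queue <- queue[-1]
      for (u in adj[[v]]$nbr) {
        if (is.na(comp[u])) { comp[u] <- cid; queue <- c(queue, u) }
      }
    }
  }
  comp
}

# Brandes single-source accumulation: exact shortest-path counting with
# dependency back-propagation. Unweighted (BFS) or weighted (Dijkstra with
# edge length 1/I_ij).
brandes_betweenness <- function(graph, weighted = FALSE) {
  n <- nrow(graph$nodes)
  adj <- adjacency_list(graph)
  bc <- rep(0, n)
  for (s in seq_len(n)) {
    sigma <- rep(0, n); sigma[s] <- 1
    dist <- rep(Inf, n); dist[s] <- 0
    pred <- vector("list", n)
    order_out <- integer(0)
    if (!weighted) {
      queue <- s
      while (length(queue) > 0L) {
        v <- queue[1]; queue <- queue[-1]
        order_out <- c(order_out, v)
        for (u in adj[[v]]$nbr) {
          if (is.infinite(dist[u])) {
            dist[u] <- dist[v] + 1
            queue <- c(queue, u)
          }
          if (dist[u] == dist[v] + 1) {
            sigma[u] <- sigma[u] + sigma[v]
            pred[[u]] <- c(pred[[u]], v)
          }
        }
      }
    } else {
      done <- rep(FALSE, n)
      repeat {
        cand <- which(!done & is.finite(dist))
        if (length(cand) == 0L) break
        v <- cand[which.min(dist[cand])]
        done[v] <- TRUE
        order_out <- c(order_out, v)
        for (k in seq_along(adj[[v]]$nbr)) {
          u <- adj[[v]]$nbr[k]
          len <- 1 / adj[[v]]$w[k]
          nd <- dist[v] + len
          if (nd < dist[u] - 1e-12) {
            dist[u] <- nd; sigma[u] <- sigma[v]; pred[[u]] <- v
          } else if (abs(nd - dist[u]) <= 1e-12) {
            sigma[u] <- sigma[u] + sigma[v]
            pred[[u]] <- c(pred[[u]], v)
          }
        }
      }
    }
    delta <- rep(0, n)
    for (v in rev(order_out)) {
      for (p in pred[[v]]) {
        delta[p] <- delta[p] + sigma[p] / sigma[v] * (1 + delta[v])
      }
      if (v != s) bc[v] <- bc[v] + delta[v]
    }
  }
  bc / 2   # undirected: each pair counted from both endpoints
}

#' Normalized betweenness profile of a residue graph
#'
#' Raw betweenness of node i is the sum over pairs (j, k), both distinct
#' from i, of g_jk(i)/g_jk (the fraction of shortest j-k paths through i),
#' computed exactly by Brandes path-count accumulation. Each node's value
#' is normalized by (N-1)(N-2)/2 with N the size of its connected
#' component; components with fewer than 3 nodes get 0.
#'
#' @param graph a `residue_graph`.
#' @param weighted use weighted shortest paths with edge length
#'   `1 / I_ij` (default FALSE: unweighted hop counts).
#' @return an object of class `betweenness_profile`: a data.frame with
#'   `node`, `chain`, `resno`, `resid`, `betweenness` (normalized, in
#'   `[0, 1]`), `raw`, `component`, `component_size`.
#' @export
betweenness <- function(graph, weighted = FALSE) {
  stopifnot(inherits(graph, "residue_graph"))
  n <- nrow(graph$nodes)
  if (n == 0L) stop("empty graph")
  raw <- brandes_betweenness(graph, weighted = weighted)
  comp <- connected_components(graph)
  csize <- as.numeric(base::table(comp))[comp]
  norm <- ifelse(csize >= 3, (csize - 1) * (csize - 2) / 2, NA_real_)
  val <- ifelse(is.na(norm), 0, raw / norm)
  out <- data.frame(node = graph$nodes$node, chain = graph$nodes$chain,
                    resno = graph$nodes$resno, resid = graph$nodes$resid,
                    betweenness = val, raw = raw, component = comp,
                    component_size = csize, stringsAsFactors = FALSE)
  class(out) <- c("betweenness_profile", "data.frame")
  out
}

#' Map mutation positions onto a betweenness profile
#'
#' @param profile a `betweenness_profile`.
#' @param positions character vector of node ids ("chain:resno") or
#'   integer residue numbers (matched on any chain).
#' @return a list with `mapped` (data.frame: position, node, betweenness,
#'   percentile within the structure) and `unresolved` (positions that
#'   matched no residue).
#' @export
map_positions <- function(profile, positions) {
  stopifnot(inherits(profile, "betweenness_profile"))
  if (length(positions) == 0L) {
    return(list(mapped = data.frame(position = character(0),
                                    node = character(0),
                                    betweenness = numeric(0),
                                    percentile = numeric(0)),
                unresolved = character(0)))
  }
  pos_chr <- as.character(positions)
  idx <- match(pos_chr, profile$node)
  by_resno <- is.na(idx) & grepl("^[0-9]+$", pos_chr)
  idx[by_resno] <- match(as.integer(pos_chr[by_resno]), profile$resno)
  resolved <- !is.na(idx)
  pct <- 100 * rank(profile$betweenness, ties.method = "max") / nrow(profile)
  mapped <- data.frame(position = pos_chr[resolved],
                       node = profile$node[idx[resolved]],
                       betweenness = profile$betweenness[idx[resolved]],
                       percentile = pct[idx[resolved]],
                       stringsAsFactors = FALSE)
  list(mapped = mapped, unresolved = pos_chr[!resolved])
}
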