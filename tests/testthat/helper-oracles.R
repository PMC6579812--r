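# Independent oracles and fixture builders used across the suite.

# Brute-force AUC: probability a random positive outscores a random
# negative, ties counting one half. O(n_pos * n_neg).
auc_oracle <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Brute-force raw betweenness by exhaustive shortest-path enumeration:
# BFS hop distances, then explicit DFS enumeration of every shortest path
# per pair, counting interior occurrences. Independent of the Brandes
# accumulation in the package.
betweenness_oracle <- function(n, edges) {
  adj <- lapply(seq_len(n), function(v) integer(0))
  if (nrow(edges) > 0) {
    for (r in seq_len(nrow(edges))) {
      i <- edges[r, 1]; j <- edges[r, 2]
      adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
    }
  }
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    D[s, s] <- 0; q <- s
    while (length(q) > 0) {
      v <- q[1]; q <- q[-1]
      for (u in adj[[v]]) if (is.infinite(D[s, u])) {
        D[s, u] <- D[s, v] + 1; q <- c(q, u)
      }
    }
  }
  all_paths <- function(j, k) {
    if (j == k) return(list(j))
    out <- list()
    for (u in adj[[j]]) {
      if (is.finite(D[u, k]) && D[u, k] == D[j, k] - 1) {
        for (p in all_paths(u, k)) out[[length(out) + 1]] <- c(j, p)
      }
    }
    out
  }
  raw <- rep(0, n)
  for (j in seq_len(n - 1)) for (k in seq(j + 1, n)) {
    if (!is.finite(D[j, k]) || D[j, k] < 2) next
    ps <- all_paths(j, k)
    interior <- unlist(lapply(ps, function(p) p[-c(1, length(p))]))
    tb <- base::table(interior)
    raw[as.integer(names(tb))] <- raw[as.integer(names(tb))] +
      as.numeric(tb) / length(ps)
  }
  raw
}

# random simple graph with n nodes and each pair connected with prob p
random_edges <- function(n, p, seed) {
  set.seed(seed)
  pairs <- t(combn(n, 2))
  pairs[runif(nrow(pairs)) < p, , drop = FALSE]
}

# tiny fixture genome: named lowercase sequences -> ref_store + FASTA
fixture_store <- function(seqs) {
  structure(vapply(seqs, tolower, ""), class = "ref_store")
}

write_fixture_fasta <- function(seqs, path = tempfile(fileext = ".fa")) {
  con <- file(path, "w")
  for (nm in names(seqs)) {
    writeLines(c(paste0(">", nm), seqs[[nm]]), con)
  }
  close(con)
  path
}

# minimal PDB writer: one CA-like atom per residue at given coordinates,
# plus optional extra atoms; enough structure for contact counting
write_fixture_pdb <- function(residues, path = tempfile(fileext = ".pdb")) {
  # residues: list of lists with chain, resno, atoms = matrix x,y,z
  lines <- character(0)
  serial <- 0
  atom_names <- c("CA", "CB", "CG", "CD", "CE", "CZ", "NZ", "OD")
  for (res in residues) {
    for (a in seq_len(nrow(res$atoms))) {
      serial <- serial + 1
      nm <- atom_names[(a - 1) %% length(atom_names) + 1]
      lines <- c(lines, sprintf(
        "ATOM  %5d  %-3s GLY %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
        serial, nm, res$chain, res$resno,
        res$atoms[a, 1], res$atoms[a, 2], res$atoms[a, 3],
        substr(nm, 1, 1)))
    }
  }
  writeLines(c(lines, "END"), path)
  path
}

# small labeled sequence dataset for CNN tests: motif-planted synthetic
# data at reduced scale, returning an encoded_dataset
fixture_encoded <- function(n_total = 300, q = 1, seed = 1,
                            scheme = "onehot", w = 10) {
  frac_driver <- 6389 / 19330
  spec <- synth_spec(n_drivers = round(n_total * frac_driver),
                     n_passengers = round(n_total * (1 - frac_driver)),
                     n_chrom = 2, chrom_length = max(5000, n_total * 25),
                     w = w, q = q, seed = seed)
  sim <- simulate_dataset(spec, seed = seed)
  pairs <- extract_pairs(sim$store, sim$variants, w = w)
  encode_dataset(pairs, scheme)
}
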