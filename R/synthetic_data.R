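#' @title Synthetic genomes, motif-planted variants and score tables
#' @description Fully self-contained generator of benchmark data with the
#'   statistical structure the pipeline assumes: a uniform-background
#'   multi-chromosome genome, driver/passenger variants where drivers
#'   carry a planted sequence motif near the variant site with tunable
#'   probability, and class-conditional "ensemble-like" feature columns
#'   with tunable separation and inter-feature correlation. The sequence
#'   signal and the tabular signal are generated independently, so the
#'   marginal contribution of the DL score in fusion is assertable.
#' @name synthetic_data
NULL

#' Specify a synthetic dataset
#'
#' Defaults reproduce the 6,389 driver / 12,941 passenger class imbalance
#' of the study composition; `scale` shrinks both counts proportionally
#' for fast experiments.
#'
#' @param n_drivers,n_passengers class counts (defaults 6389 / 12941).
#' @param scale multiplier applied to both default counts (default 1).
#' @param n_chrom number of chromosomes (default 4).
#' @param chrom_length length of each chromosome in bp (default 250000).
#' @param w window radius the variants will be extracted with
#'   (default 10); variant sites are spaced so windows never overlap.
#' @param motif planted driver motif, lowercase, shorter than the window
#'   (default `"tgacgt"`, a 6-mer learnable by short convolutions).
#' @param q probability that a driver carries the planted motif
#'   (default 1); passengers are never planted.
#' @param ensemble_features names of class-separated score columns
#'   (default `RadialSVM`, `LR`).
#' @param separation driver-minus-passenger mean shift of each ensemble
#'   column in SD units (default 1.5; single-column AUC about 0.86).
#' @param correlation latent Gaussian correlation between ensemble
#'   columns (default 0.5).
#' @param noise_features names of class-independent N(0,1) columns
#'   (default `GerpRS`, `LRT`, `verPhyloP`, `SiPhy`, `GerpN`).
#' @param seed default RNG seed for the generators.
#' @return an object of class `synth_spec`.
#' @export
synth_spec <- function(n_drivers = 6389L, n_passengers = 12941L, scale = 1,
                       n_chrom = 4L, chrom_length = 250000L, w = 10L,
                       motif = "tgacgt", q = 1,
                       ensemble_features = c("RadialSVM", "LR"),
                       separation = 1.5, correlation = 0.5,
                       noise_features = c("GerpRS", "LRT", "verPhyloP",
                                          "SiPhy", "GerpN"),
                       seed = 1L) {
  n_drivers <- max(1L, as.integer(round(n_drivers * scale)))
  n_passengers <- max(1L, as.integer(round(n_passengers * scale)))
  if (q < 0 || q > 1) stop("planting probability q must be in [0, 1]")
  if (nchar(motif) >= 2L * w + 1L) stop("motif must be shorter than the window")
  if (!grepl("^[acgt]+$", motif)) stop("motif must be a lowercase acgt string")
  if (chrom_length < 2L * w + 1L) stop("chromosomes must fit at least one window")
  structure(
    list(n_drivers = n_drivers, n_passengers = n_passengers,
         n_chrom = as.integer(n_chrom), chrom_length = as.integer(chrom_length),
         w = as.integer(w), motif = motif, q = q,
         ensemble_features = ensemble_features, separation = separation,
         correlation = correlation, noise_features = noise_features,
         seed = as.integer(seed)),
    class = "synth_spec"
  )
}

#' Generate a synthetic reference genome
#'
#' i.i.d. uniform \{a,c,g,t\} background, deterministic under the seed.
#'
#' @param spec a `synth_spec`.
#' @param seed RNG seed (default `spec$seed`).
#' @param fasta optional path; when given the genome is also written as
#'   FASTA.
#' @return a `ref_store`.
#' @export
generate_genome <- function(spec, seed = spec$seed, fasta = NULL) {
  stopifnot(inherits(spec, "synth_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  chroms <- stats::setNames(
    vapply(seq_len(spec$n_chrom), function(i) {
      paste(sample(c("a", "c", "g", "t"), spec$chrom_length, replace = TRUE),
            collapse = "")
    }, ""),
    paste0("chr", seq_len(spec$n_chrom))
  )
  store <- structure(chroms, class = "ref_store")
  if (!is.null(fasta)) write_ref_fasta(store, fasta)
  store
}

#' Write a reference store as FASTA
#' @param store a `ref_store`.
#' @param path output path.
#' @export
write_ref_fasta <- function(store, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(store)) {
    writeLines(paste0(">", nm), con)
    seq <- unclass(store)[[nm]]
    starts <- seq(1L, nchar(seq), by = 70L)
    writeLines(substring(seq, starts, pmin(starts + 69L, nchar(seq))), con)
  }
  invisible(path)
}

#' Generate labeled variants with motif planting
#'
#' Variant sites are sampled on non-overlapping window slots. For each
#' driver, with probability `q` the motif is written into the reference
#' genome at a uniform offset fully inside the variant's window (so the
#' extracted reference context contains it); passengers are never
#' planted, though background motif occurrences remain possible. The
#' variant's REF base is then read from the (possibly modified) genome
#' and ALT drawn uniformly from the other three bases.
#'
#' @param spec a `synth_spec`.
#' @param store the `ref_store` from [generate_genome()] with a matching
#'   spec.
#' @param seed RNG seed (default `spec$seed`).
#' @return a list with `variants` (data.frame: chrom, pos, ref, alt,
#'   label, planted, motif_start), `store` (the genome after planting) and
#'   `truth` (logical planted flags, for test assertions).
#' @export
generate_variants <- function(spec, store, seed = spec$seed) {
  stopifnot(inherits(spec, "synth_spec"), inherits(store, "ref_store"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed + 1L)
  w <- spec$w; L <- 2L * w + 1L
  m <- nchar(spec$motif)
  n_total <- spec$n_drivers + spec$n_passengers
  # non-overlapping slots of width L across all chromosomes
  slots_per_chrom <- spec$chrom_length %/% L
  if (slots_per_chrom * spec$n_chrom < n_total) {
    stop("genome too small for ", n_total, " non-overlapping windows")
  }
  all_slots <- expand.grid(slot = seq_len(slots_per_chrom),
                           chrom = seq_len(spec$n_chrom))
  pick <- all_slots[sample.int(nrow(all_slots), n_total), ]
  chrom <- paste0("chr", pick$chrom)
  pos <- (pick$slot - 1L) * L + w + 1L          # slot center, 1-based
  label <- sample(c(rep("driver", spec$n_drivers),
                    rep("passenger", spec$n_passengers)))
  planted <- label == "driver" & stats::runif(n_total) < spec$q
  motif_start <- rep(NA_integer_, n_total)
  seqs <- unclass(store)
  for (i in which(planted)) {
    off <- sample.int(L - m + 1L, 1L)            # window-relative start, 1-based
    st <- pos[i] - w + off - 1L                  # genomic start
    substr(seqs[[chrom[i]]], st, st + m - 1L) <- spec$motif
    motif_start[i] <- st
  }
  store <- structure(seqs, class = "ref_store")
  ref <- toupper(vapply(seq_len(n_total), function(i) {
    substr(seqs[[chrom[i]]], pos[i], pos[i])
  }, ""))
  bases <- c("A", "C", "G", "T")
  alt <- vapply(seq_len(n_total), function(i) {
    sample(setdiff(bases, ref[i]), 1L)
  }, "")
  variants <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                         label = label, planted = planted,
                         motif_start = motif_start, stringsAsFactors = FALSE)
  list(variants = variants, store = store, truth = planted)
}

# multivariate normal via Cholesky (equicorrelated latent Gaussian)
rmvn_equicorr <- function(n, k, rho) {
  Sigma <- matrix(rho, k, k); diag(Sigma) <- 1
  Z <- matrix(stats::rnorm(n * k), nrow = n)
  Z %*% chol(Sigma)
}

#' Generate a class-conditional feature table
#'
#' Ensemble-like columns are drawn from class-conditional Gaussians
#' (passenger mean 0, driver mean `spec$separation`, unit SD) with the
#' configured latent correlation; noise columns are class-independent
#' N(0,1). The table is keyed by [variant_key()].
#'
#' @param spec a `synth_spec`.
#' @param variants the variant data.frame from [generate_variants()].
#' @param seed RNG seed (default `spec$seed`).
#' @return a data.frame with columns `key`, `label`, the ensemble
#'   features and the noise features.
#' @export
generate_feature_table <- function(spec, variants, seed = spec$seed) {
  stopifnot(inherits(spec, "synth_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed + 2L)
  n <- nrow(variants)
  ke <- length(spec$ensemble_features)
  if (ke > 0L) {
    E <- rmvn_equicorr(n, ke, spec$correlation)
    shift <- ifelse(variants$label == "driver", spec$separation, 0)
    E <- E + shift
    colnames(E) <- spec$ensemble_features
  } else E <- NULL
  kn <- length(spec$noise_features)
  if (kn > 0L) {
    Nz <- matrix(stats::rnorm(n * kn), nrow = n,
                 dimnames = list(NULL, spec$noise_features))
  } else Nz <- NULL
  keys <- vapply(seq_len(n), function(i) variant_key(variants[i, ]), "")
  out <- data.frame(key = keys, label = variants$label,
                    stringsAsFactors = FALSE)
  if (!is.null(E)) out <- cbind(out, as.data.frame(E))
  if (!is.null(Nz)) out <- cbind(out, as.data.frame(Nz))
  out
}

#' Generate a full synthetic dataset
#'
#' Convenience wrapper chaining [generate_genome()],
#' [generate_variants()] and [generate_feature_table()]; optionally
#' writes FASTA, variant TSV, feature TSV and a ground-truth JSON to a
#' directory.
#'
#' @param spec a `synth_spec`.
#' @param seed RNG seed (default `spec$seed`).
#' @param dir optional output directory.
#' @return a list with `store`, `variants`, `features`, `truth`.
#' @export
simulate_dataset <- function(spec, seed = spec$seed, dir = NULL) {
  store <- generate_genome(spec, seed)
  gv <- generate_variants(spec, store, seed)
  features <- generate_feature_table(spec, gv$variants, seed)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_ref_fasta(gv$store, file.path(dir, "genome.fasta"))
    utils::write.table(gv$variants[, c("chrom", "pos", "ref", "alt", "label")],
                       file.path(dir, "variants.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(features, file.path(dir, "features.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(planted = gv$truth, motif = spec$motif, q = spec$q),
      file.path(dir, "truth.json"), auto_unbox = TRUE)
  }
  list(store = gv$store, variants = gv$variants, features = features,
       truth = gv$truth)
}
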