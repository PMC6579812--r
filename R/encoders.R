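#' @title Numeric encodings of mutation-pair matrices
#' @description The three preprocessing schemes that turn a 2 x L symbol
#'   matrix into numbers: label encoding (one integer ID per nucleotide),
#'   one-hot encoding (a 5-bit indicator block per nucleotide) and a learned
#'   2-dimensional skip-gram embedding per nucleotide.
#' @name encoders
NULL

# Label IDs follow alphabetical symbol order: a=0, c=1, g=2, n=3, t=4.
LABEL_IDS <- stats::setNames(0:4, c("a", "c", "g", "n", "t"))

# One-hot slot order within each 5-bit block. Reading a block left to
# right answers "how many n, g, t, c, a are at this position", so
# 'a' -> [0,0,0,0,1] and 'c' -> [0,0,0,1,0].
ONEHOT_SLOTS <- c("n", "g", "t", "c", "a")

pair_chars <- function(pair) {
  stopifnot(inherits(pair, "mutation_pair"))
  rbind(strsplit(pair$ref_row, "")[[1]], strsplit(pair$alt_row, "")[[1]])
}

check_alphabet <- function(ch) {
  bad <- setdiff(unique(as.vector(ch)), names(LABEL_IDS))
  if (length(bad) > 0L) {
    stop("symbol(s) outside alphabet {a,c,g,n,t}: ", paste(bad, collapse = ", "))
  }
}

new_encoded_sample <- function(scheme, mat, pair) {
  structure(
    list(scheme = scheme, matrix = mat,
         label = pair$variant$label,
         key = variant_key(pair$variant), w = pair$w),
    class = "encoded_sample"
  )
}

#' Canonical string key for a variant
#' @param v a variant row or `mutation_pair$variant` list.
#' @return string `"chrom:pos:REF>ALT"`.
#' @export
variant_key <- function(v) {
  sprintf("%s:%d:%s>%s", v$chrom, as.integer(v$pos),
          toupper(v$ref), toupper(v$alt))
}

#' Label-encode a mutation pair
#'
#' Each nucleotide is replaced by its integer ID under the fixed
#' alphabetical map a->0, c->1, g->2, n->3, t->4, yielding a 2 x L integer
#' matrix.
#'
#' @param pair a `mutation_pair`.
#' @return an `encoded_sample` with scheme `"label"` and a 2 x L matrix.
#' @export
encode_label <- function(pair) {
  ch <- pair_chars(pair)
  check_alphabet(ch)
  mat <- matrix(LABEL_IDS[ch], nrow = 2L)
  new_encoded_sample("label", mat, pair)
}

#' One-hot encode a mutation pair
#'
#' Each nucleotide expands to a 5-bit indicator block in slot order
#' (n, g, t, c, a); each row of the result is the concatenation of L such
#' blocks, so the matrix is 2 x 5L.
#'
#' @param pair a `mutation_pair`.
#' @param slots block slot order; the default follows the convention that
#'   'a' -> `[0,0,0,0,1]` and 'c' -> `[0,0,0,1,0]`.
#' @return an `encoded_sample` with scheme `"onehot"` and a 2 x 5L matrix.
#' @export
encode_onehot <- function(pair, slots = ONEHOT_SLOTS) {
  stopifnot(setequal(slots, names(LABEL_IDS)), length(slots) == 5L)
  ch <- pair_chars(pair)
  check_alphabet(ch)
  L <- ncol(ch)
  mat <- matrix(0L, nrow = 2L, ncol = 5L * L)
  slot_of <- stats::setNames(seq_along(slots), slots)
  for (r in 1:2) {
    idx <- (seq_len(L) - 1L) * 5L + slot_of[ch[r, ]]
    mat[r, idx] <- 1L
  }
  out <- new_encoded_sample("onehot", mat, pair)
  out$slots <- slots
  out
}

#' Train a skip-gram nucleotide embedding
#'
#' A word2vec-style skip-gram model with negative sampling over the
#' 5-symbol vocabulary \{a,c,g,n,t\}, trained on single-nucleotide tokens
#' of the supplied sequences. Symbols never seen in the corpus keep a zero
#' vector (with a warning). Training is deterministic given `seed` and the
#' corpus order.
#'
#' @param corpus character vector of lowercase sequences (e.g. the
#'   reference rows of extracted pairs).
#' @param dims embedding dimensionality (default 2).
#' @param seed RNG seed.
#' @param window skip-gram context radius in tokens (default 5).
#' @param epochs passes over the corpus (default 3).
#' @param lr initial learning rate, decayed linearly to 10% (default 0.05).
#' @param negative number of negative samples per positive pair (default 3).
#' @return an object of class `embedding_model`: a list with `vectors`
#'   (5 x dims matrix, rows named by symbol), `dims`, `seed` and a corpus
#'   descriptor.
#' @export
train_embedding <- function(corpus, dims = 2L, seed = 1L, window = 5L,
                            epochs = 3L, lr = 0.05, negative = 3L) {
  if (length(corpus) == 0L || all(!nzchar(corpus))) stop("empty corpus")
  vocab <- names(LABEL_IDS)
  toks <- lapply(tolower(corpus), function(s) strsplit(s, "")[[1]])
  bad <- setdiff(unique(unlist(toks)), vocab)
  if (length(bad) > 0L) stop("corpus symbol(s) outside vocabulary: ",
                             paste(bad, collapse = ", "))
  counts <- table(factor(unlist(toks), levels = vocab))
  # unigram^(3/4) negative-sampling distribution over seen symbols
  neg_p <- as.numeric(counts)^0.75
  if (sum(neg_p) == 0) stop("empty corpus")
  neg_p <- neg_p / sum(neg_p)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  W_in  <- matrix(stats::runif(5L * dims, -0.5, 0.5) / dims, nrow = 5L,
                  dimnames = list(vocab, NULL))
  W_out <- matrix(0, nrow = 5L, ncol = dims, dimnames = list(vocab, NULL))
  seen <- as.numeric(counts) > 0
  W_in[!seen, ] <- 0

  sigm <- function(z) 1 / (1 + exp(-pmin(pmax(z, -30), 30)))
  total_steps <- max(1L, epochs * sum(lengths(toks)))
  step <- 0L
  for (ep in seq_len(epochs)) {
    for (tk in toks) {
      n <- length(tk)
      if (n < 2L) next
      ids <- LABEL_IDS[tk] + 1L
      for (i in seq_len(n)) {
        step <- step + 1L
        alpha <- lr * max(0.1, 1 - step / total_steps)
        lo <- max(1L, i - window); hi <- min(n, i + window)
        ctx <- ids[setdiff(lo:hi, i)]
        if (length(ctx) == 0L) next
        wi <- ids[i]
        v <- W_in[wi, ]
        neg <- sample.int(5L, negative * length(ctx), replace = TRUE, prob = neg_p)
        targets <- c(ctx, neg)
        y <- c(rep(1, length(ctx)), rep(0, length(neg)))
        U <- W_out[targets, , drop = FALSE]
        g <- (sigm(U %*% v) - y) * alpha        # gradient scale per target
        dv <- crossprod(U, g)
        W_out[targets, ] <- U - as.numeric(g) %*% t(v)
        W_in[wi, ] <- v - as.numeric(dv)
      }
    }
  }
  if (any(!seen)) {
    warning("symbol(s) absent from training corpus keep a zero vector: ",
            paste(vocab[!seen], collapse = ", "))
  }
  structure(
    list(vectors = W_in, dims = as.integer(dims), seed = as.integer(seed),
         corpus = sprintf("%d sequence(s), %d tokens", length(corpus),
                          sum(lengths(toks)))),
    class = "embedding_model"
  )
}

# save/restore global RNG state so seeded helpers do not clobber callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' @export
print.embedding_model <- function(x, ...) {
  cat(sprintf("Nucleotide embedding (%d-d, seed %d; %s)\n",
              x$dims, x$seed, x$corpus))
  print(round(x$vectors, 4))
  invisible(x)
}

#' Embed a mutation pair
#'
#' Each nucleotide is replaced by its learned `dims`-vector, concatenated
#' along the row, giving a 2 x (dims * L) matrix (2 x 2L at the default
#' dimensionality).
#'
#' @param pair a `mutation_pair`.
#' @param model an `embedding_model` from [train_embedding()].
#' @return an `encoded_sample` with scheme `"embedding"`.
#' @export
encode_embedding <- function(pair, model) {
  stopifnot(inherits(model, "embedding_model"))
  ch <- pair_chars(pair)
  check_alphabet(ch)
  miss <- setdiff(unique(as.vector(ch)), rownames(model$vectors))
  if (length(miss) > 0L) stop("symbol(s) missing from embedding vocabulary: ",
                              paste(miss, collapse = ", "))
  d <- model$dims
  mat <- matrix(0, nrow = 2L, ncol = d * ncol(ch))
  for (r in 1:2) {
    mat[r, ] <- as.vector(t(model$vectors[ch[r, ], , drop = FALSE]))
  }
  out <- new_encoded_sample("embedding", mat, pair)
  out$dims <- d
  out
}

#' Decode a label- or one-hot-encoded sample back to its mutation pair
#'
#' Exact inverse of [encode_label()] / [encode_onehot()]. Embedding samples
#' are not invertible in general and raise an error.
#'
#' @param sample an `encoded_sample`.
#' @return a `mutation_pair` (without the original variant coordinates'
#'   store context, but with identical rows, radius and variant fields).
#' @export
decode <- function(sample) {
  stopifnot(inherits(sample, "encoded_sample"))
  if (sample$scheme == "embedding") {
    stop("embedding samples cannot be decoded")
  }
  mat <- sample$matrix
  if (sample$scheme == "label") {
    id2sym <- names(LABEL_IDS)
    rows <- apply(mat, 1, function(r) paste(id2sym[r + 1L], collapse = ""))
  } else {
    slots <- if (!is.null(sample$slots)) sample$slots else ONEHOT_SLOTS
    L <- ncol(mat) / 5L
    rows <- apply(mat, 1, function(r) {
      blocks <- matrix(r, nrow = 5L)
      if (!all(colSums(blocks) == 1L)) stop("malformed one-hot block")
      paste(slots[apply(blocks, 2, which.max)], collapse = "")
    })
  }
  w <- sample$w
  v <- strsplit(sample$key, "[:>]")[[1]]
  structure(
    list(w = w, ref_row = rows[1], alt_row = rows[2],
         variant = list(chrom = v[1], pos = as.integer(v[2]),
                        ref = v[3], alt = v[4], label = sample$label)),
    class = "mutation_pair"
  )
}

#' Encode a list of pairs into a dataset for CNN training
#'
#' Stacks per-pair encodings into a channels-first numeric array suitable
#' for [train_evaluate_cv()] and friends. The 2 symbol rows become input
#' channels; block encodings are unpacked so that convolution slides along
#' the L nucleotide positions: label gives 2 channels x L, one-hot
#' 10 channels x L (5 bits per row), embedding `2*dims` channels x L.
#'
#' @param pairs list of `mutation_pair` objects.
#' @param scheme `"label"`, `"onehot"` or `"embedding"`.
#' @param model an `embedding_model`, required for scheme `"embedding"`.
#' @return a list of class `encoded_dataset`: `x` (array n x C x L),
#'   `y` (integer 0/1 labels, driver = 1, NA when unlabeled), `keys`,
#'   `scheme`, `w`.
#' @export
encode_dataset <- function(pairs, scheme = c("label", "onehot", "embedding"),
                           model = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(length(pairs) > 0L)
  w <- pairs[[1]]$w
  L <- 2L * w + 1L
  enc1 <- function(p) {
    if (p$w != w) stop("all pairs must share one window radius")
    switch(scheme,
      label = {
        s <- encode_label(p)
        # center the 0..4 IDs so the net starts from zero-mean inputs
        (s$matrix - 2) / 2
      },
      onehot = {
        s <- encode_onehot(p)
        rbind(matrix(s$matrix[1, ], nrow = 5L), matrix(s$matrix[2, ], nrow = 5L))
      },
      embedding = {
        if (is.null(model)) stop("scheme 'embedding' requires a model")
        s <- encode_embedding(p, model)
        d <- model$dims
        rbind(matrix(s$matrix[1, ], nrow = d), matrix(s$matrix[2, ], nrow = d))
      }
    )
  }
  mats <- lapply(pairs, enc1)
  C <- nrow(mats[[1]])
  x <- array(0, dim = c(length(pairs), C, L))
  for (i in seq_along(mats)) x[i, , ] <- mats[[i]]
  labels <- vapply(pairs, function(p) p$variant$label, "")
  y <- ifelse(labels == "driver", 1L, ifelse(labels == "passenger", 0L, NA_integer_))
  structure(
    list(x = x, y = y, keys = vapply(pairs, function(p) variant_key(p$variant), ""),
         scheme = scheme, w = w),
    class = "encoded_dataset"
  )
}
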