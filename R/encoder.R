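# Token codes: A=1 C=2 G=3 T=4, any other IUPAC/error character=5 (ambiguity),
# pad=6. The pad token maps to a fixed zero vector at the base-embedding
# layer, so padding behaves like the convolutions' zero padding.
TOK_AMBIG <- 5L
TOK_PAD <- 6L

#' Encode a DNA string as token indices
#'
#' A/C/G/T map to four tokens; any other character (IUPAC ambiguity codes,
#' read errors) maps to a single ambiguity token; the result is right-padded
#' with the pad token to `max_len`. Longer sequences are truncated with a
#' warning.
#'
#' @param seq non-empty DNA string.
#' @param max_len padded length.
#' @return integer vector of length `max_len` with attributes
#'   `original_length` and `truncated`.
#' @export
encode_sequence <- function(seq, max_len = 128L) {
  if (!is.character(seq) || length(seq) != 1 || nchar(seq) == 0) {
    stop("sequence must be a single non-empty string")
  }
  enc <- encode_sequences(seq, max_len)
  out <- enc[1, ]
  attr(out, "original_length") <- attr(enc, "original_length")[1]
  attr(out, "truncated") <- attr(enc, "truncated")[1]
  out
}

#' Encode many DNA strings into a token matrix
#'
#' @param seqs character vector of non-empty DNA strings.
#' @param max_len padded length.
#' @return integer matrix (sequences x `max_len`), plus `original_length` and
#'   `truncated` attributes.
#' @export
encode_sequences <- function(seqs, max_len = 128L) {
  if (length(seqs) == 0) stop("no sequences to encode")
  if (any(nchar(seqs) == 0)) stop("empty sequence cannot be encoded")
  max_len <- as.integer(max_len)
  lens <- nchar(seqs)
  truncated <- lens > max_len
  if (any(truncated)) {
    warning(sum(truncated), " sequence(s) longer than max_len = ", max_len,
            " truncated")
  }
  lut <- rep(TOK_AMBIG, 256L)
  lut[utf8ToInt("A")] <- 1L; lut[utf8ToInt("C")] <- 2L
  lut[utf8ToInt("G")] <- 3L; lut[utf8ToInt("T")] <- 4L
  lut[utf8ToInt("a")] <- 1L; lut[utf8ToInt("c")] <- 2L
  lut[utf8ToInt("g")] <- 3L; lut[utf8ToInt("t")] <- 4L
  out <- matrix(TOK_PAD, length(seqs), max_len)
  for (i in seq_along(seqs)) {
    l <- min(lens[i], max_len)
    out[i, seq_len(l)] <- lut[utf8ToInt(substr(seqs[i], 1L, l))]
  }
  attr(out, "original_length") <- pmin(lens, max_len)
  attr(out, "truncated") <- truncated
  out
}

#' Initialize a DNA encoder model
#'
#' The architecture: a learnable base-character embedding; two 1-D
#' convolutions with kernel size 5 — the first with stride/dilation 1 and
#' symmetric zero padding 2 (scans every contiguous 5-mer), the second with
#' dilation 5 and symmetric zero padding 10 (integrates positions farther
#' apart) — each followed by ReLU and both preserving sequence length; then a
#' two-layer MLP head (hidden width `hidden_dim`, ReLU between the layers)
#' that aggregates the convolutional features into the final embedding.
#'
#' @param embed_dim output dimension; must equal the species-embedding
#'   dimension.
#' @param base_dim width of the learnable base-character embedding.
#' @param channels channel width of both convolutional layers.
#' @param hidden_dim MLP hidden width.
#' @param max_len padded input length; must be >= 21 so the dilated kernel
#'   fits.
#' @param aggregation how conv features enter the MLP: `"flatten"` keeps
#'   positional information (channels x max_len features); `"mean_pool"`
#'   averages over positions.
#' @param seed RNG seed for weight initialization.
#' @return object of class `phyloshot_dna_encoder` (untrained).
#' @export
new_dna_encoder <- function(embed_dim = 64, base_dim = 8, channels = 64,
                            hidden_dim = 2048, max_len = 128,
                            aggregation = c("flatten", "mean_pool"),
                            seed = 1) {
  aggregation <- match.arg(aggregation)
  max_len <- as.integer(max_len)
  if (max_len < 21) stop("max_len must be >= 21 so the dilated kernel fits")
  set.seed(seed)
  gi <- function(fan_in, ...) {
    dims <- c(...)
    array(rnorm(prod(dims), sd = sqrt(2 / fan_in)), dim = dims)
  }
  feat_in <- if (aggregation == "flatten") channels * max_len else channels
  params <- list(
    E  = gi(4, 5, base_dim),                 # 5 learnable rows; pad row fixed 0
    W1 = gi(5 * base_dim, 5, base_dim, channels),  b1 = numeric(channels),
    W2 = gi(5 * channels, 5, channels, channels),  b2 = numeric(channels),
    W3 = gi(feat_in, feat_in, hidden_dim),         b3 = numeric(hidden_dim),
    W4 = gi(hidden_dim, hidden_dim, embed_dim),    b4 = numeric(embed_dim)
  )
  structure(list(
    params = params,
    embed_dim = as.integer(embed_dim), base_dim = as.integer(base_dim),
    channels = as.integer(channels), hidden_dim = as.integer(hidden_dim),
    max_len = max_len, aggregation = aggregation,
    trained = FALSE, loss_trace = NULL, train_config = NULL
  ), class = "phyloshot_dna_encoder")
}

# Shift the l-major (B*L x C) representation by `off` positions along the
# sequence axis, filling with zeros (the convolutions' symmetric zero pad).
shift_rows <- function(X, off, B, L) {
  if (off == 0) return(X)
  Y <- matrix(0, B * L, ncol(X))
  if (off > 0) {
    if (off < L) Y[seq_len((L - off) * B), ] <- X[(off * B + 1):(L * B), ]
  } else {
    off <- -off
    if (off < L) Y[(off * B + 1):(L * B), ] <- X[seq_len((L - off) * B), ]
  }
  Y
}

conv1d_forward <- function(X, W, b, offsets, B, L) {
  Y <- matrix(b, B * L, length(b), byrow = TRUE)
  for (k in seq_along(offsets)) {
    Y <- Y + shift_rows(X, offsets[k], B, L) %*% W[k, , ]
  }
  Y
}

conv1d_backward <- function(dY, X, W, offsets, B, L) {
  dW <- array(0, dim = dim(W))
  dX <- matrix(0, nrow(X), ncol(X))
  for (k in seq_along(offsets)) {
    dW[k, , ] <- crossprod(shift_rows(X, offsets[k], B, L), dY)
    dX <- dX + shift_rows(dY, -offsets[k], B, L) %*% t(W[k, , ])
  }
  list(dW = dW, db = colSums(dY), dX = dX)
}

OFFS1 <- -2:2          # kernel 5, dilation 1, pad 2
OFFS2 <- seq(-10, 10, by = 5)  # kernel 5, dilation 5, pad 10

# Full forward pass; returns the output and, optionally, the caches needed
# for backprop. tokens: B x max_len integer matrix.
encoder_forward_full <- function(model, tokens, keep_cache = FALSE) {
  p <- model$params
  B <- nrow(tokens); L <- model$max_len
  if (ncol(tokens) != L) {
    stop("encoded length ", ncol(tokens), " does not match model max_len ", L)
  }
  Eext <- rbind(p$E, 0)                    # pad token -> zero vector
  X0 <- Eext[as.vector(tokens), , drop = FALSE]   # (B*L) x base_dim, l-major
  Z1 <- conv1d_forward(X0, p$W1, p$b1, OFFS1, B, L)
  A1 <- Z1 * (Z1 > 0)
  Z2 <- conv1d_forward(A1, p$W2, p$b2, OFFS2, B, L)
  A2 <- Z2 * (Z2 > 0)
  stopifnot(nrow(A2) == B * L)             # length preservation
  if (model$aggregation == "flatten") {
    Fm <- matrix(array(A2, c(B, L, model$channels)), B, L * model$channels)
  } else {
    Fm <- matrix(0, B, model$channels)
    for (l in seq_len(L)) Fm <- Fm + A2[((l - 1) * B + 1):(l * B), , drop = FALSE]
    Fm <- Fm / L
  }
  Z3 <- Fm %*% p$W3 + matrix(p$b3, B, model$hidden_dim, byrow = TRUE)
  A3 <- Z3 * (Z3 > 0)
  out <- A3 %*% p$W4 + matrix(p$b4, B, model$embed_dim, byrow = TRUE)
  if (!keep_cache) return(out)
  list(out = out, tokens = tokens, X0 = X0, Z1 = Z1, A1 = A1, Z2 = Z2,
       A2 = A2, Fm = Fm, Z3 = Z3, A3 = A3, B = B, L = L)
}

# Backprop from d(out) through the whole network; returns gradient list
# matching model$params.
encoder_backward <- function(model, cache, dOut) {
  p <- model$params
  B <- cache$B; L <- cache$L
  dA3 <- dOut %*% t(p$W4)
  gW4 <- crossprod(cache$A3, dOut); gb4 <- colSums(dOut)
  dZ3 <- dA3 * (cache$Z3 > 0)
  gW3 <- crossprod(cache$Fm, dZ3); gb3 <- colSums(dZ3)
  dF <- dZ3 %*% t(p$W3)
  if (model$aggregation == "flatten") {
    dA2 <- matrix(array(dF, c(B, L, model$channels)), B * L, model$channels)
  } else {
    dA2 <- matrix(0, B * L, model$channels)
    for (l in seq_len(L)) dA2[((l - 1) * B + 1):(l * B), ] <- dF / L
  }
  dZ2 <- dA2 * (cache$Z2 > 0)
  c2 <- conv1d_backward(dZ2, cache$A1, p$W2, OFFS2, B, L)
  dZ1 <- c2$dX * (cache$Z1 > 0)
  c1 <- conv1d_backward(dZ1, cache$X0, p$W1, OFFS1, B, L)
  # base-embedding gradient: scatter dX0 rows by token; pad row dropped
  gE <- rowsum(c1$dX, group = as.vector(cache$tokens))
  gEfull <- matrix(0, 5, model$base_dim)
  keep <- as.integer(rownames(gE))
  keep_ok <- keep <= 5L
  gEfull[keep[keep_ok], ] <- gE[keep_ok, , drop = FALSE]
  list(E = gEfull, W1 = c1$dW, b1 = c1$db, W2 = c2$dW, b2 = c2$db,
       W3 = gW3, b3 = gb3, W4 = gW4, b4 = gb4)
}

#' Forward pass of the DNA encoder
#'
#' Maps encoded sequences to embedding-space vectors. Both convolutional
#' stages preserve the padded sequence length.
#'
#' @param model a `phyloshot_dna_encoder`.
#' @param encoded an integer token vector from [encode_sequence()] or a token
#'   matrix from [encode_sequences()]; padded length must equal the model's
#'   `max_len`.
#' @return numeric matrix (sequences x `embed_dim`); a single vector input
#'   yields a 1-row matrix.
#' @export
encoder_forward <- function(model, encoded) {
  if (is.vector(encoded)) encoded <- matrix(encoded, nrow = 1)
  encoder_forward_full(model, encoded, keep_cache = FALSE)
}

#' Embed raw sequences with a DNA encoder
#'
#' Convenience wrapper: tokenize then run [encoder_forward()].
#'
#' @param model a `phyloshot_dna_encoder`.
#' @param sequences character vector of DNA strings.
#' @return numeric matrix (sequences x `embed_dim`).
#' @export
embed_sequences <- function(model, sequences) {
  encoder_forward(model, encode_sequences(sequences, model$max_len))
}

#' Cosine-distance mapping loss for one sequence
#'
#' The training loss of the encoder: the cosine distance between the
#' network's output for a sequence and the frozen phylogenetic embedding of
#' its species.
#'
#' @param model_output numeric vector (the encoder output).
#' @param species_vec numeric vector (the species' fixed embedding).
#' @return scalar in \[0, 2\].
#' @export
dna_mapping_loss <- function(model_output, species_vec) {
  cosine_distance(as.numeric(model_output), as.numeric(species_vec))
}
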