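#' Embedding backend
#'
#' Maps a log-Mel patch to a fixed-length 1024-dimensional embedding.
#' Two backends share one contract (dimension, determinism, finiteness):
#'
#' * `"projection"` — a fixed, seed-determined random linear projection of
#'   the flattened patch followed by a ReLU. Cheap, fully offline and
#'   bitwise reproducible; the backend used for training and testing on
#'   synthetic audio.
#' * `"pretrained"` — the published pretrained audio-event network, whose
#'   penultimate-layer outputs are the transfer-learning embeddings. Its
#'   weights and runtime are an optional external dependency; when they are
#'   not available [embed()] raises a "backend unavailable" error that
#'   points to the projection backend.
#'
#' @param type `"projection"` or `"pretrained"`.
#' @param seed Integer seed fixing the projection weights.
#' @param weights_path Optional path to pretrained weights (pretrained
#'   backend only).
#' @param embedding_dim Embedding width; 1024 for both shipped backends.
#' @return An object of class `embedding_backend`.
#' @export
embedding_backend <- function(type = c("projection", "pretrained"),
                              seed = 20250912L, weights_path = NULL,
                              embedding_dim = 1024L) {
  type <- match.arg(type)
  structure(list(type = type, seed = as.integer(seed),
                 weights_path = weights_path,
                 embedding_dim = as.integer(embedding_dim)),
            class = "embedding_backend")
}

#' @export
print.embedding_backend <- function(x, ...) {
  cat(sprintf("<embedding_backend '%s'> dim=%d seed=%d\n",
              x$type, x$embedding_dim, x$seed))
  invisible(x)
}

# Fixed projection weights, generated once per (seed, in_dim, out_dim) and
# cached; regenerating from the same seed is bitwise identical.
.projection_weights <- function(backend, in_dim) {
  key <- paste("proj", backend$seed, in_dim, backend$embedding_dim, sep = "_")
  W <- .swallowseg_cache[[key]]
  if (is.null(W)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(backend$seed)
    W <- matrix(rnorm(in_dim * backend$embedding_dim) / sqrt(in_dim),
                nrow = in_dim)
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    .swallowseg_cache[[key]] <- W
  }
  W
}

#' Embed one log-Mel patch
#'
#' @param backend An [embedding_backend()].
#' @param patch A time x mel matrix as returned by [log_mel()].
#' @return Numeric embedding vector of length `backend$embedding_dim`.
#' @export
embed <- function(backend, patch) {
  as.vector(embed_patches(backend, matrix(as.vector(patch), nrow = 1L)))
}

#' Embed many patches at once
#'
#' @param backend An [embedding_backend()].
#' @param patches n x (time*mel) matrix; each row is a flattened patch
#'   (column-major flattening of the time x mel matrix, as `as.vector()`
#'   produces).
#' @return n x embedding_dim matrix.
#' @export
embed_patches <- function(backend, patches) {
  if (backend$type == "pretrained") {
    if (is.null(backend$weights_path) || !file.exists(backend$weights_path %||% ""))
      stop("pretrained embedding backend unavailable (no weights/runtime); ",
           "use embedding_backend(\"projection\") instead")
    stop("pretrained embedding backend requires an external network runtime ",
         "that is not bundled; use embedding_backend(\"projection\") instead")
  }
  if (!is.matrix(patches)) patches <- matrix(patches, nrow = 1L)
  W <- .projection_weights(backend, ncol(patches))
  E <- patches %*% W
  E[E < 0] <- 0
  E
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Concatenate an embedding with the frame's zero-crossing rate
#'
#' @param emb Embedding vector (length 1024 for the shipped backends).
#' @param zcr Zero-crossing rate in `[0, 1]`.
#' @return Numeric vector of length `length(emb) + 1`; the ZCR is the last
#'   element, appended unscaled (it already lies in `[0, 1]`).
#' @export
make_feature_vector <- function(emb, zcr) {
  if (!is.numeric(zcr) || length(zcr) != 1L || is.na(zcr) || zcr < 0 || zcr > 1)
    stop("zcr must be a single value in [0, 1]")
  c(as.numeric(emb), zcr)
}
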