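## Embedding-based statistics: perceptual similarity and PCA-space norms.
## The network producing the embeddings is outside the package; any per-image
## fixed-length vectors with category labels plug in here.

#' Bundle per-image embedding vectors
#'
#' @param vectors numeric matrix, one row per image (all rows the same
#'   length), or a data.frame of numeric columns.
#' @param image_ids unique image identifiers (row order).
#' @param true_category category label per image.
#' @param predicted_category optional classifier output per image; used by
#'   the `restrict_correct` option of the similarity statistics.
#' @param layer_tag label of the representation (`"blk1"`, `"blk5"`,
#'   `"fc2"`, or arbitrary).
#' @return An `embedding_set` object.
#' @export
embedding_set <- function(vectors, image_ids, true_category,
                          predicted_category = NULL, layer_tag = "blk5") {
  vectors <- as.matrix(vectors)
  stopifnot(nrow(vectors) == length(image_ids),
            length(true_category) == length(image_ids))
  if (anyDuplicated(image_ids)) stop("image_ids must be unique")
  rownames(vectors) <- as.character(image_ids)
  structure(list(vectors = vectors, image_ids = as.character(image_ids),
                 true_category = as.character(true_category),
                 predicted_category = if (is.null(predicted_category)) NULL
                 else as.character(predicted_category),
                 layer_tag = layer_tag),
            class = "embedding_set")
}

#' Read/write an embedding set as delimited text
#'
#' One row per image; `image_id`, `true_category`, optional
#' `predicted_category`, then the feature columns.
#' @param path CSV path.
#' @param layer_tag stored tag (read side).
#' @return An `embedding_set` / `path` invisibly.
#' @export
read_embeddings <- function(path, layer_tag = "blk5") {
  df <- read.csv(path, stringsAsFactors = FALSE)
  pred <- if ("predicted_category" %in% names(df)) df$predicted_category
  feat <- df[setdiff(names(df), c("image_id", "true_category",
                                  "predicted_category"))]
  embedding_set(as.matrix(feat), df$image_id, df$true_category, pred,
                layer_tag)
}

#' @rdname read_embeddings
#' @param e an `embedding_set`.
#' @export
write_embeddings <- function(e, path) {
  df <- data.frame(image_id = e$image_ids, true_category = e$true_category,
                   stringsAsFactors = FALSE)
  if (!is.null(e$predicted_category))
    df$predicted_category <- e$predicted_category
  df <- cbind(df, as.data.frame(e$vectors, row.names = FALSE))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

.similarity <- function(e, image_id, same_category, restrict_correct) {
  stopifnot(inherits(e, "embedding_set"))
  ids <- e$image_ids
  keep <- rep(TRUE, length(ids))
  if (restrict_correct) {
    if (is.null(e$predicted_category))
      stop("restrict_correct requires predicted_category labels")
    keep <- e$predicted_category == e$true_category
  }
  i <- match(as.character(image_id), ids)
  if (is.na(i)) stop("unknown image_id: ", image_id)
  if (!keep[i]) return(NA_real_)  # misclassified images are not analysed
  same <- e$true_category == e$true_category[i]
  others <- which(keep & (if (same_category) same else !same))
  others <- setdiff(others, i)
  if (!length(others)) return(NA_real_)
  mean(vapply(others, function(j) cor(e$vectors[i, ], e$vectors[j, ]),
              numeric(1)))
}

#' Within-category perceptual similarity
#'
#' Mean Pearson correlation between an image's embedding vector and the
#' vectors of all other images of the same category.  With
#' `restrict_correct = TRUE`, only correctly classified images (per
#' `predicted_category`) enter the comparison, and misclassified query
#' images return `NA`.  Category singletons return `NA`.
#'
#' @param e an [embedding_set()].
#' @param image_id query image.
#' @param restrict_correct restrict to correctly classified images.
#' @return Mean correlation (or `NA`).
#' @export
within_similarity <- function(e, image_id, restrict_correct = FALSE) {
  .similarity(e, image_id, same_category = TRUE, restrict_correct)
}

#' Across-category perceptual similarity
#'
#' As [within_similarity()], with the comparison set complemented: all other
#' images from *different* categories.
#' @inheritParams within_similarity
#' @export
across_similarity <- function(e, image_id, restrict_correct = FALSE) {
  .similarity(e, image_id, same_category = FALSE, restrict_correct)
}

#' PCA-space L2 norms of embedding vectors
#'
#' Fits a principal-component rotation on the full embedding matrix
#' (mean-centering, no scaling), retains all components (100% variance),
#' and returns the Euclidean norm of every image's score vector.  Because
#' the rotation is orthogonal, each norm equals the distance of the centered
#' original vector from the origin.
#'
#' @param e an [embedding_set()] with at least 2 images.
#' @return Named numeric vector of norms (by image id).
#' @export
pca_l2_norms <- function(e) {
  stopifnot(inherits(e, "embedding_set"))
  if (nrow(e$vectors) < 2) stop("need at least 2 images for PCA")
  if (all(apply(e$vectors, 2, var) == 0))
    return(setNames(rep(0, nrow(e$vectors)), e$image_ids))
  pc <- prcomp(e$vectors, center = TRUE, scale. = FALSE)
  setNames(sqrt(rowSums(pc$x^2)), e$image_ids)
}

#' Per-image embedding statistics table
#'
#' Convenience wrapper assembling, for every image, within-/across-category
#' similarity from one reference layer and PCA-space norms from up to three
#' layers, in the shape consumed by [compute_image_stats()].
#'
#' @param sets named list of [embedding_set()] objects; similarity
#'   statistics are taken from `sim_layer`, norms from layers named
#'   `blk1`, `blk5`, `fc2` when present.
#' @param sim_layer layer used for the similarity statistics.
#' @param restrict_correct passed to the similarity functions.
#' @return data.frame keyed by `image_id` with columns `within_sim`,
#'   `across_sim`, `blk1_l2`, `blk5_l2`, `fc2_l2` (missing layers give NA).
#' @export
embedding_statistics <- function(sets, sim_layer = "blk5",
                                 restrict_correct = FALSE) {
  ref <- sets[[sim_layer]]
  if (is.null(ref)) stop("sim_layer not found in sets")
  ids <- ref$image_ids
  ws <- vapply(ids, function(i) within_similarity(ref, i, restrict_correct),
               numeric(1))
  as <- vapply(ids, function(i) across_similarity(ref, i, restrict_correct),
               numeric(1))
  out <- data.frame(image_id = ids, within_sim = ws, across_sim = as,
                    stringsAsFactors = FALSE, row.names = NULL)
  for (tag in c("blk1", "blk5", "fc2")) {
    col <- paste0(tag, "_l2")
    out[[col]] <- if (!is.null(sets[[tag]])) {
      nm <- pca_l2_norms(sets[[tag]])
      unname(nm[ids])
    } else NA_real_
  }
  out
}
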