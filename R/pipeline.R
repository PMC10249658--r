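# High-level pipeline wrappers: corpus -> training set, structure ->
# predicted sites.

#' Build a training set from structure files
#'
#' Parses and annotates every file, enumerates per-nucleotide images and
#' Gaussian label grids from the experimentally bound (or planted) Mg
#' ions.
#'
#' @param files PDB file paths.
#' @param cfg a [grid_config()].
#' @return list with `images`, `labels`, and `structure_idx` (which file
#'   each image came from).
#' @export
load_training_set <- function(files, cfg = grid_config()) {
  images <- list(); labels <- list(); idx <- integer(0)
  for (f in seq_along(files)) {
    s <- assign_attributes(read_structure(files[f]))
    en <- enumerate_images(s, cfg, with_labels = TRUE)
    images <- c(images, en$images)
    labels <- c(labels, en$labels)
    idx <- c(idx, rep(f, length(en$images)))
  }
  list(images = images, labels = labels, structure_idx = idx)
}

#' Predict ranked Mg2+ sites for one structure
#'
#' Runs the full pipeline: per-nucleotide voxelization, network
#' prediction, assembly of the overlapping grids into a global field,
#' and DBSCAN/k-means site extraction.
#'
#' @param model a trained `mg_model`.
#' @param structure an annotated `rna_structure` (or a file path).
#' @param cfg a [grid_config()] matching the training geometry.
#' @param threshold,eps,min_samples,seed see [extract_sites()].
#' @return a ranked site table.
#' @export
predict_structure <- function(model, structure, cfg = grid_config(),
                              threshold = 0.5, eps = 2.0, min_samples = 4,
                              seed = 1) {
  if (is.character(structure))
    structure <- assign_attributes(read_structure(structure))
  en <- enumerate_images(structure, cfg)
  grids <- lapply(en$images, function(im) predict_grid(model, im))
  field <- assemble_field(grids)
  extract_sites(field, threshold = threshold, eps = eps,
                min_samples = min_samples, seed = seed)
}

#' Evaluate predictions over a corpus directory
#'
#' Predicts sites for every PDB file and pools hits against each file's
#' bound Mg ions.
#'
#' @param model a trained `mg_model`.
#' @param files PDB file paths.
#' @param cfg a [grid_config()].
#' @param cutoff hit distance cutoff (A).
#' @param ... passed to [predict_structure()].
#' @return list with the pooled `eval_report`-style counts (`tpr`, `ppv`,
#'   `n_hit`, `n_true`, `n_pred`) and per-structure tables `pred_list`,
#'   `true_list`.
#' @export
evaluate_corpus <- function(model, files, cfg = grid_config(),
                            cutoff = 3.0, ...) {
  pred_list <- vector("list", length(files))
  true_list <- vector("list", length(files))
  nh <- 0L; nt <- 0L; np <- 0L
  for (f in seq_along(files)) {
    s <- assign_attributes(read_structure(files[f]))
    pred <- predict_structure(model, s, cfg, ...)
    truth <- bound_ions(s)
    m <- match_sites(pred, truth, cutoff)
    nh <- nh + nrow(m$pairs)
    nt <- nt + nrow(truth)
    np <- np + nrow(pred)
    pred_list[[f]] <- pred
    true_list[[f]] <- truth
  }
  r <- rates_from_counts(nh, nt, np)
  list(tpr = r$tpr, ppv = r$ppv, n_hit = nh, n_true = nt, n_pred = np,
       pred_list = pred_list, true_list = true_list)
}
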