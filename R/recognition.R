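## Template preparation ------------------------------------------------------

#' Add a template column to a cohort manifest
#'
#' Computes one template per manifest row. For the `"gei"` variant the
#' silhouettes are rendered from the skeleton sequence first (capsule body
#' model) and averaged; for the GSI variants the full skeleton pipeline
#' runs.
#'
#' @param manifest Tibble from [make_cohort()] with a `sequence` list
#'   column, or with a `file` column of JSON-lines paths.
#' @param cfg A [gsi_config()].
#' @return The manifest with an added `template` list column.
#' @export
add_templates <- function(manifest, cfg = gsi_config()) {
  seqs <- if ("sequence" %in% names(manifest)) {
    manifest$sequence
  } else {
    lapply(manifest$file, read_sequence)
  }
  manifest$template <- lapply(seqs, function(s) {
    if (cfg$variant == "gei")
      compute_gei(simulate_silhouettes(s, canvas_w = cfg$canvas_w,
                                       canvas_h = cfg$canvas_h,
                                       margin = cfg$margin),
                  canvas_w = cfg$canvas_w, canvas_h = cfg$canvas_h,
                  margin = cfg$margin)
    else
      compute_gsi(s, cfg)
  })
  manifest
}

## LOTO protocol -------------------------------------------------------------

#' Train a model under a protocol split
#'
#' Thin wrapper over [train_gait_cnn()] taking a manifest with a `template`
#' column. Errors if the manifest holds a single identity.
#'
#' @param manifest Manifest rows to train on (must carry `template` and
#'   `subject`).
#' @param cfg A [train_config()].
#' @param val_manifest Optional validation rows for early stopping.
#' @return A trained `gait_cnn`.
#' @export
train <- function(manifest, cfg = train_config(), val_manifest = NULL) {
  if (length(unique(manifest$subject)) < 2L)
    stop("training manifest holds a single identity", call. = FALSE)
  train_gait_cnn(manifest$template, manifest$subject,
                 val_templates = if (!is.null(val_manifest))
                   val_manifest$template,
                 val_labels = if (!is.null(val_manifest))
                   val_manifest$subject,
                 cfg = cfg)
}

#' Leave-one-trial-out evaluation
#'
#' Closed-set classification accuracy (%) of the softmax over the held-out
#' trials: identities were seen in training, the trials were not.
#'
#' @param manifest Manifest with `template`, `subject` and `trial` columns.
#' @param model A trained `gait_cnn`.
#' @param test_trials Trial numbers that form the held-out set.
#' @return Accuracy in percent (scalar).
#' @export
evaluate_loto <- function(manifest, model, test_trials = 9:10) {
  test <- manifest[manifest$trial %in% test_trials, ]
  if (nrow(test) == 0L) stop("no test trials present in the manifest",
                             call. = FALSE)
  pred <- predict(model, test$template, type = "class")
  100 * mean(pred == test$subject)
}

#' Run the leave-one-trial-out protocol end to end
#'
#' Trains on trials `1..7` with trial 8 as the per-subject validation split
#' (the last training trial), evaluates on trials 9-10.
#'
#' @param manifest Manifest with templates (see [add_templates()]).
#' @param cfg A [train_config()] with `protocol = "loto"`.
#' @param train_trials,val_trials,test_trials Trial partition.
#' @return List with `model`, `accuracy` (%), and the split sizes.
#' @export
run_loto <- function(manifest, cfg = train_config("loto"),
                     train_trials = 1:7, val_trials = 8L,
                     test_trials = 9:10) {
  tr <- manifest[manifest$trial %in% train_trials, ]
  va <- manifest[manifest$trial %in% val_trials, ]
  model <- train(tr, cfg, val_manifest = va)
  acc <- evaluate_loto(manifest, model, test_trials = test_trials)
  list(model = model, accuracy = acc,
       n_train = nrow(tr), n_val = nrow(va),
       n_test = sum(manifest$trial %in% test_trials))
}

## Gallery / probe protocol --------------------------------------------------

cosine_distance <- function(A, B) {
  ## rows of A (probes) vs rows of B (gallery)
  An <- A / pmax(sqrt(rowSums(A^2)), 1e-12)
  Bn <- B / pmax(sqrt(rowSums(B^2)), 1e-12)
  1 - An %*% t(Bn)
}

#' Gallery/probe rank-1 identification
#'
#' Embeds every template with the model's penultimate layer and assigns each
#' probe the identity of its nearest gallery embedding under cosine
#' distance (ties broken by the lowest gallery index). Rank-1 accuracy is
#' computed for every (gallery view, probe view, covariate) cell; identities
#' are expected to be unseen during training.
#'
#' @param gallery,probe Manifests with `template`, `subject`, `view_deg` and
#'   (probe) `covariate` columns. Probe identities must all appear in the
#'   gallery.
#' @param model A trained `gait_cnn` used as the embedding function.
#' @return An `identification_report`: `cells` tibble (one row per cell with
#'   `rank1` in percent and `n_probes`), `cross_view` (named list of
#'   gallery-view x probe-view matrices, one per covariate), and `views`.
#' @export
evaluate_gallery_probe <- function(gallery, probe, model) {
  missing_ids <- setdiff(unique(probe$subject), unique(gallery$subject))
  if (length(missing_ids))
    stop("probe identities missing from gallery: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  gemb <- predict(model, gallery$template, type = "embedding")
  pemb <- predict(model, probe$template, type = "embedding")
  views <- sort(unique(c(gallery$view_deg, probe$view_deg)))
  covs <- unique(probe$covariate)
  cells <- list()
  for (cv in covs) {
    for (gv in views) {
      gi <- which(gallery$view_deg == gv)
      if (!length(gi)) next
      for (pv in views) {
        pidx <- which(probe$view_deg == pv & probe$covariate == cv)
        if (!length(pidx)) next
        D <- cosine_distance(pemb[pidx, , drop = FALSE],
                             gemb[gi, , drop = FALSE])
        nn <- apply(D, 1, which.min)   # which.min: lowest index on ties
        hit <- gallery$subject[gi][nn] == probe$subject[pidx]
        cells[[length(cells) + 1L]] <- tibble::tibble(
          covariate = cv, gallery_view = gv, probe_view = pv,
          rank1 = 100 * mean(hit), n_probes = length(pidx))
      }
    }
  }
  cells <- do.call(rbind, cells)
  cross_view <- lapply(stats::setNames(covs, covs), function(cv) {
    m <- matrix(NA_real_, length(views), length(views),
                dimnames = list(gallery = views, probe = views))
    sub <- cells[cells$covariate == cv, ]
    m[cbind(match(sub$gallery_view, views), match(sub$probe_view, views))] <-
      sub$rank1
    m
  })
  structure(list(cells = cells, cross_view = cross_view, views = views),
            class = "identification_report")
}

#' @export
print.identification_report <- function(x, ...) {
  cat(sprintf("<identification_report> %d views, covariates: %s\n",
              length(x$views),
              paste(names(x$cross_view), collapse = ", ")))
  for (cv in names(x$cross_view)) {
    s <- summarize_matrix(x$cross_view[[cv]])
    cat(sprintf("  %s: same-view mean %.1f%%, all-pairs mean %.1f%%\n",
                cv, s$diagonal_mean, s$grand_mean))
  }
  invisible(x)
}

#' @rdname evaluate_gallery_probe
#' @param x An `identification_report`.
#' @param ... Unused.
#' @export
tidy.identification_report <- function(x, ...) x$cells

#' @rdname evaluate_gallery_probe
#' @export
glance.identification_report <- function(x, ...) {
  do.call(rbind, lapply(names(x$cross_view), function(cv) {
    s <- summarize_matrix(x$cross_view[[cv]])
    tibble::tibble(covariate = cv, same_view_mean = s$diagonal_mean,
                   cross_view_mean = s$offdiag_mean,
                   grand_mean = s$grand_mean)
  }))
}

## Matrix and covariate arithmetic -------------------------------------------

#' Summarize a cross-view rank-1 matrix
#'
#' Pure arithmetic over a square gallery-view x probe-view matrix: per-row
#' and per-column means, diagonal (same-view) mean, mean of the column
#' means, mean over all entries, and mean over strictly off-diagonal
#' (cross-view) entries. Rounding is left to the caller.
#'
#' @param m Square numeric matrix of rank-1 rates (%).
#' @return List with `row_means`, `col_means`, `diagonal_mean`,
#'   `mean_of_col_means`, `grand_mean`, `offdiag_mean`.
#' @export
summarize_matrix <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop("cross-view summaries need a square matrix", call. = FALSE)
  off <- m[row(m) != col(m)]
  list(row_means = rowMeans(m), col_means = colMeans(m),
       diagonal_mean = mean(diag(m)),
       mean_of_col_means = mean(colMeans(m)),
       grand_mean = mean(m), offdiag_mean = mean(off))
}

#' Covariate degradation table
#'
#' From per-condition same-view mean accuracies, computes each method's
#' overall mean across NM/BG/CL and the degradation of each non-NM
#' condition relative to normal walking, in percentage points.
#'
#' @param same_view_means Data frame with a `method` column and numeric
#'   `NM`, `BG`, `CL` columns (%), or a named numeric vector for a single
#'   method.
#' @return Tibble with columns `method`, `NM`, `BG`, `CL`, `mean`,
#'   `deg_BG`, `deg_CL` (degradations are `condition - NM`, negative for a
#'   drop).
#' @export
covariate_report <- function(same_view_means) {
  if (is.numeric(same_view_means))
    same_view_means <- data.frame(method = "method",
                                  as.list(same_view_means))
  if (!"NM" %in% names(same_view_means))
    stop("covariate table lacks the NM (normal walking) column",
         call. = FALSE)
  conds <- intersect(c("NM", "BG", "CL"), names(same_view_means))
  vals <- as.matrix(same_view_means[, conds, drop = FALSE])
  tibble::tibble(
    method = same_view_means$method,
    NM = same_view_means$NM,
    BG = if ("BG" %in% conds) same_view_means$BG else NA_real_,
    CL = if ("CL" %in% conds) same_view_means$CL else NA_real_,
    mean = rowMeans(vals),
    deg_BG = if ("BG" %in% conds) same_view_means$BG - same_view_means$NM
             else NA_real_,
    deg_CL = if ("CL" %in% conds) same_view_means$CL - same_view_means$NM
             else NA_real_)
}

## Published benchmark tables ------------------------------------------------

#' Published CASIA-B benchmark aggregates
#'
#' Cross-view rank-1 matrices (seven views, NM gallery vs NM probe) for the
#' joint-based GSI and the GEI baseline, and the same-view covariate table,
#' as published for the CASIA-B benchmark. Each cross-view table carries the
#' published per-row/per-column means alongside the cell entries; the
#' published 90-degree column mean of the joint-based table (30.01) differs
#' from the mean of its printed column entries (31.44), so summaries
#' recomputed from entries will not always coincide with the printed means.
#'
#' @return List with `gsi_joints` and `gei` (each: `matrix` 7x7,
#'   `printed_col_means`, `printed_row_means`, `printed_grand_mean`) and
#'   `covariates` (data frame method x NM/BG/CL).
#' @export
published_benchmarks <- function() {
  load_cv <- function(f) {
    d <- utils::read.csv(system.file("extdata", f, package = "gsigait",
                                     mustWork = TRUE), check.names = FALSE)
    rn <- d[[1]]
    m <- as.matrix(d[, -1])
    views <- rn[rn != "printed_mean"]
    entries <- m[rn != "printed_mean", colnames(m) != "printed_mean"]
    dimnames(entries) <- list(gallery = views,
                              probe = sub("^p", "", colnames(entries)))
    list(matrix = entries,
         printed_col_means = m[rn == "printed_mean",
                               colnames(m) != "printed_mean"],
         printed_row_means = m[rn != "printed_mean",
                               colnames(m) == "printed_mean"],
         printed_grand_mean = m[rn == "printed_mean",
                                colnames(m) == "printed_mean"])
  }
  list(gsi_joints = load_cv("crossview_rank1_gsi_joints.csv"),
       gei = load_cv("crossview_rank1_gei.csv"),
       covariates = utils::read.csv(
         system.file("extdata", "covariate_same_view_rank1.csv",
                     package = "gsigait", mustWork = TRUE)))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
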