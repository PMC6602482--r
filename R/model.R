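# Training and application of the six-feature antigenicity scorer:
# iterative shell-feature filtering, consolidator training, weighted ridge
# logistic regression, neighborhood calibration and thresholding.

#' Pipeline configuration defaults
#'
#' @param surface_threshold Relative-SASA cutoff for surface residues.
#' @param probe_radius SASA probe radius (Angstrom).
#' @param n_points SASA sample points per atom.
#' @param triangle_dist Unit-triangle edge cutoff (Angstrom).
#' @param contact_dist Contact-graph cutoff for clustering coefficient and
#'   consolidated AAindex neighborhoods (Angstrom).
#' @param shell_radius,shell_step Shell-model radius and layer width.
#' @param calib_dist Calibration neighborhood distance (Angstrom).
#' @param contact_cutoff Antibody heavy-atom contact cutoff for epitope
#'   labels (Angstrom).
#' @param epsilon Pseudo-frequency in the propensity log-odds.
#' @param lambda L2 penalty of the logistic regression.
#' @param ann_hidden,ann_epochs Consolidator size and training length.
#' @param filter_folds Cross-validation folds inside the iterative filter.
#' @param min_improve AUC improvement needed to keep adding shell features.
#' @param threshold Default decision cutoff on the calibrated score (the
#'   shipped server default 0.089; retrained models store their own).
#' @param include_self Include the target residue in the calibration
#'   average (guarantees a nonempty neighborhood).
#' @return Named list of settings.
#' @export
ep3_config <- function(surface_threshold = 0.15, probe_radius = 1.4,
                       n_points = 960L, triangle_dist = 15,
                       contact_dist = 15, shell_radius = 10, shell_step = 2,
                       calib_dist = 5, contact_cutoff = 4, epsilon = 1e-6,
                       lambda = 1e-4, ann_hidden = 10L, ann_epochs = 300L,
                       filter_folds = 5L, min_improve = 1e-3,
                       threshold = 0.089, include_self = TRUE) {
  as.list(environment())
}

# ---- weighted ridge logistic regression (IRLS) ---------------------------

#' Fit a weighted L2-penalized logistic regression
#'
#' Iteratively reweighted least squares with an unpenalized intercept.
#' Hand-rolled so that single-column probe models, observation weights and
#' exact penalty semantics are available to the iterative filter.
#'
#' @param x Numeric matrix of predictors (no intercept column).
#' @param y Binary response (0/1 or logical).
#' @param weights Optional observation weights.
#' @param lambda L2 penalty on the slopes (default 1e-4).
#' @param maxit,tol IRLS iteration cap and convergence tolerance.
#' @return List with `coef` (intercept first), `converged`, `iterations`.
#' @export
fit_logistic <- function(x, y, weights = NULL, lambda = 1e-4,
                         maxit = 100L, tol = 1e-10) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (length(unique(y)) < 2) stop("labels are single-class")
  n <- nrow(x); p <- ncol(x)
  if (is.null(weights)) weights <- rep(1, n)
  w0 <- weights / mean(weights)
  X <- cbind(1, x)
  beta <- rep(0, p + 1)
  pen <- diag(c(0, rep(lambda, p)), p + 1)
  conv <- FALSE; it <- 0L
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    mu <- pmin(pmax(mu, 1e-10), 1 - 1e-10)
    W <- w0 * mu * (1 - mu)
    z <- eta + (y - mu) / (mu * (1 - mu))
    XtW <- t(X * W)
    newbeta <- tryCatch(
      solve(XtW %*% X + pen, XtW %*% z),
      error = function(e) solve(XtW %*% X + pen + diag(1e-8, p + 1),
                                XtW %*% z)
    )
    newbeta <- unname(drop(newbeta))
    if (max(abs(newbeta - beta)) < tol) {
      beta <- newbeta; conv <- TRUE; break
    }
    beta <- newbeta
  }
  list(coef = beta, converged = conv, iterations = it)
}

predict_logistic <- function(coef, x) {
  x <- as.matrix(x)
  1 / (1 + exp(-(coef[1] + drop(x %*% coef[-1]))))
}

# ---- iterative filtering of shell features -------------------------------

#' Greedy forward selection of shell-model features
#'
#' Starting from the empty set, repeatedly adds the candidate that
#' maximizes the cross-validated AUC of a logistic probe model; stops when
#' the improvement drops below `min_improve`. At least one feature is
#' always returned. Ties break in candidate order.
#'
#' @param candidates Numeric matrix of candidate features (named columns).
#' @param labels Binary labels.
#' @param folds CV fold count (default 5).
#' @param seed Seed for the fold split.
#' @param min_improve Minimum AUC gain to continue (default 1e-3).
#' @param lambda Probe-model L2 penalty.
#' @return Character vector of selected column names, in selection order,
#'   with attribute `cv_auc` (the AUC trace).
#' @export
iterative_filter <- function(candidates, labels, folds = 5L, seed = 1L,
                             min_improve = 1e-3, lambda = 1e-4) {
  x <- as.matrix(candidates)
  y <- as.numeric(labels)
  if (length(unique(y)) < 2) stop("labels are single-class")
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))

  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)
  fold_id <- sample(rep_len(seq_len(folds), nrow(x)))

  cv_score <- function(cols) {
    preds <- numeric(nrow(x))
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      if (length(unique(y[tr])) < 2) return(NA_real_)
      fit <- fit_logistic(x[tr, cols, drop = FALSE], y[tr], lambda = lambda)
      preds[!tr] <- predict_logistic(fit$coef, x[!tr, cols, drop = FALSE])
    }
    roc_auc(preds, y)
  }

  selected <- character(0)
  trace <- numeric(0)
  best_auc <- -Inf
  repeat {
    remaining <- setdiff(colnames(x), selected)
    if (length(remaining) == 0) break
    aucs <- vapply(remaining, function(cand) {
      cv_score(c(selected, cand))
    }, numeric(1))
    pick <- which.max(aucs)            # ties: first in candidate order
    gain <- aucs[pick] - if (length(selected)) best_auc else -Inf
    if (length(selected) > 0 && (is.na(gain) || gain < min_improve)) break
    selected <- c(selected, remaining[pick])
    best_auc <- aucs[pick]
    trace <- c(trace, best_auc)
  }
  attr(selected, "cv_auc") <- trace
  selected
}

# ---- training ------------------------------------------------------------

corpus_fingerprint <- function(corpus, seed) {
  keys <- vapply(corpus, function(e) {
    paste(e$structure$pdb_id, e$structure$chain_id,
          nrow(e$structure$residues), sep = ":")
  }, character(1))
  djb2_hash(paste(c(keys, seed), collapse = ";"))
}

# tiny deterministic string hash (no crypto intent)
djb2_hash <- function(s) {
  h <- 5381
  for (ch in utf8ToInt(s)) h <- (h * 33 + ch) %% 2^31
  sprintf("%08x", h)
}

prepare_entry <- function(entry, config, subgroups, aag, agly) {
  st <- entry$structure
  if (all(is.na(st$residues$sasa))) {
    st <- compute_sasa(st, config$probe_radius, config$n_points)
  }
  if (all(is.na(st$residues$is_surface))) {
    st <- flag_surface(st, config$surface_threshold)
  }
  entry$structure <- st
  if (is.null(entry$sequons)) entry$sequons <- find_sequons(st$sequence)
  if (is.null(entry$geometry)) {
    entry$geometry <- structure_geometry(st, config, subgroups, aag, agly)
  }
  entry
}

# assemble the six-feature matrix for the surface residues of one entry
entry_features <- function(entry, model) {
  featurize(entry$structure, model, geom = entry$geometry)
}

#' Train the six-feature epitope scoring model
#'
#' Full pipeline over a labeled corpus: (1) glytri ratio and triangle
#' propensity tables; (2) the glycosylation-triangle consolidator over the
#' corpus pattern vocabulary; (3) iterative filtering of the 20 shell
#' features and the glycosylation-AAindex consolidator; (4) weighted ridge
#' logistic regression over the six per-residue classifiers; (5) default
#' threshold maximizing training balanced accuracy on calibrated scores.
#' Deterministic for a fixed seed.
#'
#' @param corpus List of entries: `structure` (`antigen_structure`),
#'   `labeling` (`epitope_labeling`), optional `sequons`, `geometry`.
#' @param config See [ep3_config()].
#' @param seed Integer seed governing all randomness.
#' @param features Character subset of the six feature names to use
#'   (ablation studies); default all six.
#' @return An `epitope_model`.
#' @export
train_epitope_model <- function(corpus, config = ep3_config(), seed = 1L,
                                features = c("avg", "apref", "cc", "index",
                                             "glytri", "glyindex")) {
  if (length(corpus) == 0) stop("empty corpus")
  subgroups <- load_subgroup_table()
  aag <- load_aaindex("general")
  agly <- load_aaindex("glyco")
  corpus <- lapply(corpus, prepare_entry, config = config,
                   subgroups = subgroups, aag = aag, agly = agly)

  small <- vapply(corpus, function(e) nrow(e$structure$residues) <= 50, TRUE)
  if (any(small)) {
    warning(sprintf("%d corpus structures have <= 50 residues", sum(small)))
  }

  labels <- unlist(lapply(corpus, function(e) {
    e$labeling$labels[e$geometry$surf]
  }))
  if (sum(labels) == 0) stop("zero epitope residues in corpus")
  if (length(labels) == 0) stop("zero surface residues in corpus")

  ratio_table <- tryCatch(
    compute_ratio_table(corpus, max_dist = config$triangle_dist,
                        subgroups = subgroups),
    error = function(e) {
      # corpora without sequons still train, with inert glyco features
      data.table(pattern = "G00-G00-G00", n_epi_glytri = 0L,
                 n_glytri = 1L, ratio = 0)
    })
  prop_table <- propensity_table(corpus, epsilon = config$epsilon,
                                 max_dist = config$triangle_dist,
                                 subgroups = subgroups)

  use_glytri <- "glytri" %in% features
  use_glyindex <- "glyindex" %in% features

  # consolidators trained against residue epitope labels, then frozen
  Wall <- do.call(rbind, lapply(corpus, function(e) {
    glytri_weight_matrix(e$geometry, ratio_table)[e$geometry$surf, ,
                                                  drop = FALSE]
  }))
  glytri_net <- if (use_glytri) {
    ann_train(Wall, labels, hidden = config$ann_hidden, seed = seed,
              epochs = config$ann_epochs)
  } else NULL

  Sall <- do.call(rbind, lapply(corpus, function(e) {
    e$geometry$shells[e$geometry$surf, , drop = FALSE]
  }))
  if (use_glyindex) {
    selection <- iterative_filter(Sall, labels, folds = config$filter_folds,
                                  seed = seed,
                                  min_improve = config$min_improve,
                                  lambda = config$lambda)
    glyindex_net <- ann_train(Sall[, selection, drop = FALSE], labels,
                              hidden = config$ann_hidden, seed = seed + 1L,
                              epochs = config$ann_epochs)
  } else {
    selection <- character(0)
    glyindex_net <- NULL
  }

  model <- structure(
    list(subgroups = subgroups, aaindex_general = aag, aaindex_glyco = agly,
         ratio_table = ratio_table, propensity_table = prop_table,
         glytri_net = glytri_net, glytri_vocab = ratio_table$pattern,
         glyindex_selection = selection, glyindex_net = glyindex_net,
         logistic = NULL, features = features, threshold = config$threshold,
         submodel_key = "general", config = config,
         provenance = list(fingerprint = corpus_fingerprint(corpus, seed),
                           seed = seed, n_structures = length(corpus))),
    class = "epitope_model"
  )

  feat <- rbindlist(lapply(corpus, entry_features, model = model))
  fx <- as.matrix(feat[, features, with = FALSE])
  ctr <- colMeans(fx)
  scl <- apply(fx, 2, sd); scl[scl < 1e-12] <- 1
  fz <- sweep(sweep(fx, 2, ctr), 2, scl, `/`)
  w <- ifelse(labels, 0.5 / mean(labels), 0.5 / mean(!labels))
  fit <- fit_logistic(fz, labels, weights = w, lambda = config$lambda)
  model$logistic <- list(coef = fit$coef, center = ctr, scale = scl,
                         converged = fit$converged)

  # default threshold: maximize training balanced accuracy on calibrated
  # scores (the shipped 0.089 applies only to the original-corpus model)
  adj <- unlist(lapply(corpus, function(e) {
    raw <- predict_raw(e$structure, model, geom = e$geometry)
    calibrate_scores(e$structure, raw, geom = e$geometry)
  }))
  grid <- unique(quantile(adj, probs = seq(0.02, 0.98, by = 0.02),
                          names = FALSE))
  ba <- vapply(grid, function(th) {
    sens <- mean(adj[labels] >= th); spec <- mean(adj[!labels] < th)
    (sens + spec) / 2
  }, numeric(1))
  model$threshold <- min(max(grid[which.max(ba)], 1e-6), 1 - 1e-6)
  model
}

#' @export
print.epitope_model <- function(x, ...) {
  cat(sprintf(
    "epitope_model (%s): %d glytri patterns, shells [%s], threshold %.3f\n",
    x$submodel_key, length(x$glytri_vocab),
    paste(x$glyindex_selection, collapse = ", "), x$threshold))
  invisible(x)
}

# ---- prediction ----------------------------------------------------------

#' Raw antigenicity scores for surface residues
#'
#' Logistic-regression probability over the (z-scored) six classifier
#' values of each surface residue.
#'
#' @param struct An `antigen_structure` with SASA and surface flags.
#' @param model Trained `epitope_model`.
#' @param geom Optional precomputed geometry.
#' @return Named numeric vector (names = residue indices) in `[0, 1]`.
#' @export
predict_raw <- function(struct, model, geom = NULL) {
  feat <- featurize(struct, model, geom = geom)
  fx <- as.matrix(feat[, model$features, with = FALSE])
  fz <- sweep(sweep(fx, 2, model$logistic$center), 2,
              model$logistic$scale, `/`)
  setNames(predict_logistic(model$logistic$coef, fz), feat$res_index)
}

#' Calibrate raw scores by the surface neighborhood average
#'
#' The adjusted score of a residue is the mean raw score over surface
#' residues within `neighbor_dist` (minimum heavy-atom distance), the
#' residue itself included, suppressing isolated false positives.
#'
#' @param struct An `antigen_structure`.
#' @param raw_scores Named vector from [predict_raw()].
#' @param neighbor_dist Neighborhood distance in Angstrom (default 5).
#' @param include_self Include the residue's own raw score (default TRUE;
#'   with FALSE, isolated residues keep their raw score).
#' @param dmat Optional distance matrix.
#' @param geom Optional precomputed geometry (used for neighbor lists when
#'   its configuration matches `neighbor_dist`).
#' @return Named numeric vector of adjusted scores over the same residues.
#' @export
calibrate_scores <- function(struct, raw_scores, neighbor_dist = 5,
                             include_self = TRUE, dmat = NULL, geom = NULL) {
  idx <- as.integer(names(raw_scores))
  nb <- NULL
  if (!is.null(geom) && geom$config$calib_dist == neighbor_dist) {
    nb <- geom$nb5
  } else {
    if (is.null(dmat)) dmat <- residue_distance_matrix(struct)
    nb <- vector("list", nrow(struct$residues))
    for (r in idx) nb[[r]] <- idx[dmat[r, idx] <= neighbor_dist]
  }
  out <- vapply(idx, function(r) {
    hood <- intersect(nb[[r]], idx)
    if (!include_self) hood <- setdiff(hood, r)
    if (length(hood) == 0) return(unname(raw_scores[as.character(r)]))
    mean(raw_scores[as.character(hood)])
  }, numeric(1))
  setNames(out, idx)
}

#' Threshold calibrated scores into epitope calls
#'
#' @param adjusted Named vector of calibrated scores (surface residues).
#' @param threshold Decision cutoff in (0, 1); a score `>= threshold` is
#'   called epitope.
#' @return Named logical vector.
#' @export
classify_epitopes <- function(adjusted, threshold = 0.089) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1) {
    stop("threshold must lie in (0, 1)")
  }
  adjusted >= threshold
}

#' Full per-residue prediction for one antigen
#'
#' Runs featurization, the logistic scorer, neighborhood calibration and
#' thresholding; non-surface residues carry `NA` scores and no call.
#'
#' @param struct An `antigen_structure` (SASA/surface computed on demand).
#' @param model Trained `epitope_model`.
#' @param threshold Optional override of the model threshold.
#' @param geom Optional precomputed geometry.
#' @return A `prediction_result` data.table: `res_index`, `seq_id`,
#'   `icode`, `aa`, `is_surface`, `raw_score`, `adjusted_score`,
#'   `predicted_epitope`.
#' @export
predict_epitopes <- function(struct, model, threshold = NULL, geom = NULL) {
  cfg <- model$config
  if (all(is.na(struct$residues$sasa))) {
    struct <- compute_sasa(struct, cfg$probe_radius, cfg$n_points)
  }
  if (all(is.na(struct$residues$is_surface))) {
    struct <- flag_surface(struct, cfg$surface_threshold)
  }
  if (is.null(threshold)) threshold <- model$threshold
  if (is.null(geom)) {
    geom <- structure_geometry(struct, cfg, model$subgroups,
                               model$aaindex_general, model$aaindex_glyco)
  }
  raw <- predict_raw(struct, model, geom = geom)
  adj <- calibrate_scores(struct, raw, neighbor_dist = cfg$calib_dist,
                          include_self = cfg$include_self, geom = geom)
  call <- classify_epitopes(adj, threshold)
  res <- struct$residues
  n <- nrow(res)
  out <- data.table(
    res_index = seq_len(n), seq_id = res$seq_id, icode = res$icode,
    aa = res$aa, is_surface = res$is_surface,
    raw_score = NA_real_, adjusted_score = NA_real_,
    predicted_epitope = NA
  )
  idx <- as.integer(names(raw))
  out[idx, `:=`(raw_score = unname(raw), adjusted_score = unname(adj),
                predicted_epitope = unname(call))]
  setattr(out, "class", c("prediction_result", class(out)))
  setattr(out, "structure_key", c(struct$pdb_id, struct$chain_id))
  setattr(out, "threshold", threshold)
  out[]
}

# ---- sub-model registry --------------------------------------------------

#' Recommend a sub-model for a host species and localization
#'
#' Deterministic fallback chain: exact (host, localization) key, then
#' host-only, then the general model.
#'
#' @param registry Named list of `epitope_model`s; keys are
#'   `"host|localization"`, `"host"` or `"general"`. Must contain
#'   `"general"`.
#' @param host Immune host species or `"unknown"`.
#' @param localization Subcellular localization or `"unknown"`.
#' @return The selected `epitope_model`.
#' @export
recommend_submodel <- function(registry, host = "unknown",
                               localization = "unknown") {
  if (length(registry) == 0) stop("empty model registry")
  if (!"general" %in% names(registry)) stop("registry lacks a general model")
  key <- paste(host, localization, sep = "|")
  if (host != "unknown" && localization != "unknown" &&
      key %in% names(registry)) {
    return(registry[[key]])
  }
  if (host != "unknown" && host %in% names(registry)) {
    return(registry[[host]])
  }
  registry[["general"]]
}

# ---- cross-validation ----------------------------------------------------

#' Structure-level cross-validated AUC of the full pipeline
#'
#' Folds are split by structure (all residues of one antigen share a fold)
#' to avoid leakage. Each fold retrains the complete model on the
#' remaining structures and scores the held-out ones; calibrated scores of
#' all held-out residues are pooled into one AUC.
#'
#' @param corpus Labeled corpus as in [train_epitope_model()].
#' @param folds Fold count (default 10).
#' @param seed Seed for the split and per-fold training.
#' @param config See [ep3_config()].
#' @param features Feature subset (ablations); default all six.
#' @return List with `auc`, `fold_table` (per-fold AUC) and pooled
#'   `scores`/`labels`.
#' @export
cv_auc <- function(corpus, folds = 10L, seed = 1L, config = ep3_config(),
                   features = c("avg", "apref", "cc", "index",
                                "glytri", "glyindex")) {
  subgroups <- load_subgroup_table()
  aag <- load_aaindex("general")
  agly <- load_aaindex("glyco")
  corpus <- lapply(corpus, prepare_entry, config = config,
                   subgroups = subgroups, aag = aag, agly = agly)
  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)
  folds <- min(folds, length(corpus))
  fold_id <- sample(rep_len(seq_len(folds), length(corpus)))

  scores <- list(); labs <- list(); fold_auc <- numeric(folds)
  for (f in seq_len(folds)) {
    train_set <- corpus[fold_id != f]
    test_set <- corpus[fold_id == f]
    model <- train_epitope_model(train_set, config = config,
                                 seed = seed + f, features = features)
    sc <- unlist(lapply(test_set, function(e) {
      raw <- predict_raw(e$structure, model, geom = e$geometry)
      calibrate_scores(e$structure, raw, geom = e$geometry,
                       neighbor_dist = config$calib_dist)
    }))
    lb <- unlist(lapply(test_set, function(e) {
      e$labeling$labels[e$geometry$surf]
    }))
    scores[[f]] <- sc; labs[[f]] <- lb
    fold_auc[f] <- if (length(unique(lb)) > 1) roc_auc(sc, lb) else NA_real_
  }
  sc <- unlist(scores); lb <- unlist(labs)
  list(auc = roc_auc(sc, lb),
       fold_table = data.table(fold = seq_len(folds), auc = fold_auc),
       scores = sc, labels = lb)
}

# ---- serialization -------------------------------------------------------

num_to_b64 <- function(x) jsonlite::base64_enc(writeBin(as.numeric(x),
                                                        raw(), size = 8))
b64_to_num <- function(s) readBin(jsonlite::base64_dec(s), numeric(),
                                  n = 1e7, size = 8)

ser_net <- function(net) {
  if (is.null(net)) return(NULL)
  list(W1 = num_to_b64(net$W1), b1 = num_to_b64(net$b1),
       W2 = num_to_b64(net$W2), b2 = num_to_b64(net$b2),
       center = num_to_b64(net$center), scale = num_to_b64(net$scale),
       dim = net$dim, hidden = length(net$b1))
}

deser_net <- function(o) {
  if (is.null(o)) return(NULL)
  d <- o$dim; h <- o$hidden
  structure(list(
    W1 = matrix(b64_to_num(o$W1), d, h), b1 = b64_to_num(o$b1),
    W2 = b64_to_num(o$W2), b2 = b64_to_num(o$b2),
    center = b64_to_num(o$center), scale = b64_to_num(o$scale), dim = d
  ), class = "ann_net")
}

#' Serialize a trained model to a versioned JSON file
#'
#' Weight arrays are base64-encoded IEEE doubles, so round-trips are
#' bit-exact.
#'
#' @param model An `epitope_model`.
#' @param path Output path.
#' @export
write_model <- function(model, path) {
  obj <- list(
    schema = "epitope3d/model", version = 1L,
    submodel_key = model$submodel_key,
    features = model$features,
    threshold = model$threshold,
    provenance = model$provenance,
    config = model$config,
    subgroups = as.list(model$subgroups),
    aaindex_general = lapply(model$aaindex_general, as.list),
    aaindex_glyco = lapply(model$aaindex_glyco, as.list),
    ratio_table = list(pattern = model$ratio_table$pattern,
                       n_epi_glytri = model$ratio_table$n_epi_glytri,
                       n_glytri = model$ratio_table$n_glytri,
                       ratio = num_to_b64(model$ratio_table$ratio)),
    propensity_table = list(pattern = model$propensity_table$pattern,
                            logodds = num_to_b64(
                              model$propensity_table$logodds)),
    glytri_net = ser_net(model$glytri_net),
    glyindex_selection = model$glyindex_selection,
    glyindex_net = ser_net(model$glyindex_net),
    logistic = list(coef = num_to_b64(model$logistic$coef),
                    center = num_to_b64(model$logistic$center),
                    scale = num_to_b64(model$logistic$scale),
                    names = model$features)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a model written by [write_model()]
#' @param path Model JSON path.
#' @return An `epitope_model`.
#' @export
read_model <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(o$schema, "epitope3d/model")) stop("not a model file")
  rt <- data.table(pattern = o$ratio_table$pattern,
                   n_epi_glytri = as.integer(o$ratio_table$n_epi_glytri),
                   n_glytri = as.integer(o$ratio_table$n_glytri),
                   ratio = b64_to_num(o$ratio_table$ratio))
  setattr(rt, "class", c("pattern_ratio_table", class(rt)))
  pt <- data.table(pattern = o$propensity_table$pattern,
                   logodds = b64_to_num(o$propensity_table$logodds))
  lg <- list(coef = b64_to_num(o$logistic$coef),
             center = setNames(b64_to_num(o$logistic$center),
                               o$logistic$names),
             scale = setNames(b64_to_num(o$logistic$scale),
                              o$logistic$names))
  cfg <- o$config
  structure(
    list(subgroups = unlist(o$subgroups),
         aaindex_general = lapply(o$aaindex_general, unlist),
         aaindex_glyco = lapply(o$aaindex_glyco, unlist),
         ratio_table = rt, propensity_table = pt,
         glytri_net = deser_net(o$glytri_net),
         glytri_vocab = rt$pattern,
         glyindex_selection = o$glyindex_selection,
         glyindex_net = deser_net(o$glyindex_net),
         logistic = lg, features = o$features,
         threshold = o$threshold, submodel_key = o$submodel_key,
         config = cfg, provenance = o$provenance),
    class = "epitope_model"
  )
}
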