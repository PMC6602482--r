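# The six per-residue classifiers and their consolidators.

make_geom <- function(st, ...) {
  structure_geometry(st, config = ep3_config(...))
}

test_that("clustering coefficient matches igraph on random geometric graphs", {
  skip_if_not_installed("igraph")
  for (rep in 1:40) {
    st <- random_cloud(sample(15:30, 1), k = 1, box = 35, seed = 900 + rep)
    geom <- make_geom(st)
    dm <- geom$dmat
    surf <- geom$surf
    A <- dm[surf, surf] <= 15
    diag(A) <- FALSE
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    want <- igraph::transitivity(g, type = "local", isolates = "zero")
    got <- vapply(surf, function(r) clustering_coeff(geom, r), numeric(1))
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("clustering coefficient degenerate cases", {
  # 4 nodes, neighbors of node 1 form a clique -> cc = 1
  st <- toy_structure(matrix(c(0, 0, 0, 10, 0, 0, 0, 10, 0, 10, 10, 0),
                             4, 3, byrow = TRUE))
  geom <- make_geom(st)
  expect_equal(clustering_coeff(geom, 1), 1.0)
  # a center with exactly one neighbor -> 0
  st2 <- toy_structure(matrix(c(0, 0, 0, 10, 0, 0, 100, 0, 0),
                              3, 3, byrow = TRUE))
  geom2 <- make_geom(st2)
  expect_equal(clustering_coeff(geom2, 1), 0)
})

test_that("shell binning matches a brute-force oracle and partitions", {
  for (rep in 1:30) {
    st <- random_cloud(sample(12:24, 1), k = 2, box = 16, seed = 1300 + rep)
    geom <- make_geom(st)
    agly <- load_aaindex("glyco")
    r <- sample(geom$surf, 1)
    prof <- shell_profile(geom, r)
    d <- geom$dmat[r, ]; d[r] <- Inf
    for (j in 1:5) {
      mem <- which(d >= 2 * (j - 1) & d < 2 * j)
      expect_equal(prof$layer_counts[j], length(mem))
      for (ki in seq_along(agly)) {
        want <- if (length(mem)) mean(agly[[ki]][st$residues$aa[mem]]) else 0
        expect_equal(unname(prof$layer_means[j, ki]), want,
                     tolerance = 1e-12)
      }
    }
    # layers partition the < 10 A neighborhood
    expect_equal(sum(prof$layer_counts), sum(d < 10))
  }
})

test_that("shell binning boundary convention is half-open", {
  # neighbor at exactly 5.0 A falls in layer 3 ([4,6)); at exactly 10 A
  # it is excluded
  st <- toy_structure(matrix(c(0, 0, 0, 5, 0, 0), 2, 3, byrow = TRUE))
  geom <- make_geom(st)
  prof <- shell_profile(geom, 1)
  expect_equal(prof$layer_counts, c(0, 0, 1, 0, 0))
  st2 <- toy_structure(matrix(c(0, 0, 0, 10, 0, 0), 2, 3, byrow = TRUE))
  prof2 <- shell_profile(make_geom(st2), 1)
  expect_equal(sum(prof2$layer_counts), 0)
  expect_true(all(prof2$layer_means == 0))
})

test_that("propensity index is zero for balanced patterns, positive for enriched", {
  corp <- make_tiny_corpus()
  pt <- propensity_table(corp)
  # residue with no triangles scores 0
  st_lonely <- toy_structure(matrix(c(0, 0, 0, 40, 0, 0, 80, 0, 0),
                                    3, 3, byrow = TRUE))
  geom_l <- make_geom(st_lonely)
  expect_equal(propensity_avg(geom_l, 1, pt), 0)

  # brute-force recomputation on a random structure
  st <- random_cloud(15, k = 1, box = 22, seed = 41)
  geom <- make_geom(st)
  for (r in sample(geom$surf, 5)) {
    tr <- enumerate_triangles(st, center = r, dmat = geom$dmat)
    want <- if (nrow(tr) == 0) 0 else {
      lo <- pt$logodds[match(tr$pattern, pt$pattern)]
      lo[is.na(lo)] <- 0
      lo[tr$has_x] <- 0
      mean(lo)
    }
    expect_equal(propensity_avg(geom, r, pt), want, tolerance = 1e-12)
  }
})

test_that("propensity sign follows enrichment", {
  # pattern at equal frequency in both classes -> log-odds ~ 0
  sq <- matrix(c(0, 0, 0, 5, 0, 0, 0, 5, 0), 3, 3, byrow = TRUE)
  st <- toy_structure(sq, aa = c("A", "A", "A"))
  lab_all <- structure(list(structure_key = c("TOYS", "A"),
                            labels = rep(TRUE, 3), n_positive = 3L,
                            n_negative_surface = 0L),
                       class = "epitope_labeling")
  corp <- list(list(structure = st, labeling = lab_all))
  pt <- propensity_table(corp)
  expect_equal(pt$f_epi, pt$f_surf)
  expect_lt(abs(pt$logodds), 1e-9)
  geom <- make_geom(st)
  expect_lt(abs(propensity_avg(geom, 1, pt)), 1e-9)
})

test_that("relative ASA preference averages the local patch", {
  # isolated residue -> its own rasa
  st <- toy_structure(matrix(c(0, 0, 0, 50, 0, 0, 100, 0, 0),
                             3, 3, byrow = TRUE), rasa = c(0.3, 0.6, 0.9))
  geom <- make_geom(st)
  expect_equal(relative_asa_pref(geom, 1), 0.3)
  # constant patch -> the constant
  stc <- toy_structure(matrix(c(0, 0, 0, 5, 0, 0, 0, 5, 0, 5, 5, 0),
                              4, 3, byrow = TRUE), rasa = rep(0.5, 4))
  expect_equal(relative_asa_pref(make_geom(stc), 2), 0.5)
  # random structure vs direct recomputation from triangle membership
  str <- random_cloud(14, k = 1, box = 20, seed = 55)
  geomr <- make_geom(str)
  tri <- geomr$triangles
  for (r in sample(geomr$surf, 5)) {
    rows <- which(tri$i == r | tri$j == r | tri$k == r)
    mem <- if (length(rows)) unique(c(r, tri$i[rows], tri$j[rows],
                                      tri$k[rows])) else r
    expect_equal(relative_asa_pref(geomr, r),
                 mean(str$residues$rasa[mem]), tolerance = 1e-12)
  }
})

test_that("consolidated AAindex equals the neighborhood table mean", {
  aag <- load_aaindex("general")
  st <- toy_structure(matrix(c(0, 0, 0, 5, 0, 0, 0, 5, 0),
                             3, 3, byrow = TRUE), aa = c("A", "A", "A"))
  geom <- make_geom(st)
  want <- mean(vapply(aag, function(v) v[["A"]], numeric(1)))
  expect_equal(consolidated_aaindex(geom, 1), want, tolerance = 1e-12)

  # brute-force recomputation on a random structure
  str <- random_cloud(16, k = 1, box = 24, seed = 66)
  geomr <- make_geom(str)
  surf <- geomr$surf
  for (r in sample(surf, 5)) {
    nb <- surf[geomr$dmat[r, surf] <= 15 & surf != r]
    hood <- c(r, nb)
    want <- mean(vapply(aag, function(v) {
      mean(v[str$residues$aa[hood]])
    }, numeric(1)))
    expect_equal(consolidated_aaindex(geomr, r), want, tolerance = 1e-12)
  }
})

test_that("glytri weights implement W_ri = ratio_i * N_occur(i)", {
  corp <- make_tiny_corpus()
  tab <- compute_ratio_table(corp)
  # S4 "ANAS": residue 4 sits in two glytri of pattern G01-G09-G10
  # (ratio 0.75 by hand count) -> weight 1.5; duplication doubles it
  geom4 <- structure_geometry(corp[[4]]$structure)
  w4 <- glytri_weights(geom4, 4, tab)
  expect_equal(unname(w4["G01-G09-G10"]), 0.75 * 2)
  expect_equal(sum(w4 > 0), 1)

  # S1 "NASK" residue 1: one glytri each of three patterns
  geom1 <- structure_geometry(corp[[1]]$structure)
  w1 <- glytri_weights(geom1, 1, tab)
  expect_equal(unname(w1["G01-G09-G10"]), 0.75)
  expect_equal(unname(w1["G01-G10-G12"]), 1.0)
  expect_equal(unname(w1["G09-G10-G12"]), 0.0)   # ratio 0

  # center with no glytri in range -> all-zero map
  st_iso <- toy_structure(matrix(c(0, 0, 0, 50, 0, 0, 100, 0, 0),
                                 3, 3, byrow = TRUE), aa = c("A", "A", "A"))
  w0 <- glytri_weights(structure_geometry(st_iso), 1, tab)
  expect_true(all(w0 == 0))
})

test_that("consolidators are deterministic, dimension-checked, monotone", {
  set.seed(1)
  x <- matrix(rnorm(400 * 3), 400, 3)
  y <- as.numeric(x[, 1] + 0.5 * rnorm(400) > 0)
  net <- ann_train(x, y, hidden = 10, seed = 3, epochs = 200)
  net2 <- ann_train(x, y, hidden = 10, seed = 3, epochs = 200)
  expect_identical(net$W1, net2$W1)       # retrain determinism

  v <- c(0.2, -0.1, 0.5)
  expect_identical(ann_predict(net, v), ann_predict(net, v))
  expect_error(ann_predict(net, c(1, 2)), "dimension mismatch")

  # all-zero input gives a fixed bias-dependent constant
  z0 <- ann_predict(net, c(0, 0, 0))
  expect_identical(ann_predict(net, c(0, 0, 0)), z0)
  expect_true(z0 > 0 && z0 < 1)

  # single-input net is a monotone transform of its input
  x1 <- matrix(rnorm(500), 500, 1)
  y1 <- as.numeric(x1[, 1] > 0)
  net1 <- ann_train(x1, y1, hidden = 10, seed = 5, epochs = 300)
  grid <- matrix(seq(-3, 3, length.out = 101), ncol = 1)
  out <- ann_predict(net1, grid)
  expect_true(all(diff(out) > -1e-9))
})

test_that("consolidate wrappers validate vocabularies", {
  corp <- make_tiny_corpus()
  tab <- compute_ratio_table(corp)
  set.seed(2)
  W <- matrix(abs(rnorm(40 * nrow(tab))), 40)
  yy <- rep(c(0, 1), 20)
  net <- ann_train(W, yy, seed = 1, epochs = 50)
  w <- setNames(numeric(nrow(tab)), tab$pattern)
  expect_silent(consolidate_glytri(w, net, tab$pattern))
  expect_error(consolidate_glytri(w[-1], net, tab$pattern[-1]),
               "dimension mismatch")

  sel <- c("KIMC930101_L1", "LAWE840101_L2")
  net2 <- ann_train(matrix(rnorm(80), 40, 2), yy, seed = 1, epochs = 50)
  sv <- setNames(rnorm(20), as.vector(vapply(
    names(load_aaindex("glyco")),
    function(a) paste0(a, "_L", 1:5), character(5))))
  expect_silent(consolidate_glyindex(sv, sel, net2))
  expect_error(consolidate_glyindex(sv, c(sel, "KIMC930101_L3"), net2),
               "dimension mismatch")
})

test_that("featurize yields six finite features per surface residue", {
  corp <- generate_corpus(4, synth_spec(n_residues = 60), seed = 8)
  model <- train_epitope_model(corp$entries, seed = 2)
  e <- corp$entries[[1]]
  ft <- featurize(e$structure, model)
  expect_equal(nrow(ft), sum(e$structure$residues$is_surface))
  feature_cols <- c("avg", "apref", "cc", "index", "glytri", "glyindex")
  expect_true(all(feature_cols %in% colnames(ft)))
  expect_equal(ncol(ft[, ..feature_cols]), 6L)
  m <- as.matrix(ft[, ..feature_cols])
  expect_true(all(is.finite(m)))
  expect_true(all(ft$cc >= 0 & ft$cc <= 1))
  expect_true(all(ft$glytri >= 0))
  # determinism across repeated calls
  ft2 <- featurize(e$structure, model)
  expect_identical(ft, ft2)
})

test_that("all six features are rigid-motion invariant", {
  corp <- generate_corpus(4, synth_spec(n_residues = 60), seed = 8)
  model <- train_epitope_model(corp$entries, seed = 2)
  e <- corp$entries[[2]]
  ft <- featurize(e$structure, model)
  str2 <- rigid_transform(e$structure)
  str2$residues[, `:=`(sasa = NA_real_, rasa = NA_real_, is_surface = NA)]
  str2 <- flag_surface(compute_sasa(str2), 0.15)
  ft2 <- featurize(str2, model)
  expect_equal(ft2$avg, ft$avg, tolerance = 1e-6)
  expect_equal(ft2$cc, ft$cc, tolerance = 1e-6)
  expect_equal(ft2$glytri, ft$glytri, tolerance = 1e-6)
  expect_equal(ft2$glyindex, ft$glyindex, tolerance = 1e-6)
  expect_equal(ft2$apref, ft$apref, tolerance = 1e-6)
  expect_equal(ft2$index, ft$index, tolerance = 1e-6)
})
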