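test_that("structure fingerprints are 2048-bit, deterministic and spelling-invariant", {
  fp <- structural_fingerprint(c("CCO", "C(C)O", "c1ccccc1O"),
                               keys = c("a", "b", "c"))
  expect_identical(dim(fp), c(3L, 2048L))
  expect_true(all(fp %in% c(0, 1)))
  expect_identical(attr(fp, "space_tag"), "structure")
  expect_identical(unname(fp["a", ]), unname(fp["b", ]))   # same molecule
  expect_false(all(fp["a", ] == fp["c", ]))
  expect_true(sum(fp["a", ]) >= 1 && sum(fp["a", ]) <= 2048)
  fp2 <- structural_fingerprint("CCO", keys = "a")
  expect_identical(unname(fp2[1, ]), unname(fp[1, ]))      # repeatable
})

test_that("tanimoto follows the set algebra", {
  a <- c(1, 1, 1, 0, 0); b <- c(0, 1, 1, 1, 0)
  expect_equal(tanimoto(a, b), 0.5)        # 2 shared / 4 union
  expect_equal(tanimoto(a, a), 1.0)
  expect_equal(tanimoto(c(1, 0), c(0, 1)), 0)
  expect_equal(tanimoto(c(0, 0), c(0, 0)), 0)   # all-zero convention
  expect_equal(tanimoto(a, b), tanimoto(b, a))
  expect_error(tanimoto(a, c(1, 0)), "mismatch")
})

test_that("physicochemical descriptors recover hand-computable values", {
  d <- physchem_descriptors(c("CCO", "c1ccccc1"), keys = c("etoh", "benzene"))
  expect_equal(unname(d["etoh", "mol_weight"]), 46.07, tolerance = 1e-3)
  expect_equal(unname(d["etoh", "hba"]), 1)
  expect_equal(unname(d["etoh", "n_atoms"]), 3)
  expect_equal(unname(d["benzene", "n_rings"]), 1)
  expect_equal(unname(d["benzene", "frac_aromatic"]), 1)
  cleaned <- clean_descriptor_matrix(d)
  expect_true(all(is.finite(cleaned)))
})

test_that("descriptor cleanup drops failing columns and clips residual infinities", {
  m <- cbind(ok = c(1, 2, 3), bad = c(1, NaN, 2), inf = c(1, Inf, 2))
  out <- clean_descriptor_matrix(m)
  expect_identical(colnames(out), "ok")
  expect_setequal(attr(out, "dropped"), c("bad", "inf"))
  out2 <- clean_descriptor_matrix(m, drop_any = FALSE)
  expect_true(all(is.finite(out2)))
  expect_equal(unname(out2[2, "inf"]), 2)   # +Inf clipped to finite max
  expect_equal(unname(out2[2, "bad"]), 1)   # NaN clipped to finite min
})

test_that("one-hot annotation encoding uses the sorted vocabulary", {
  rec <- list(c1 = c("A"), c2 = c("B"), c3 = c("A", "B"), c4 = character(0))
  m <- onehot_annotations(rec)
  expect_identical(colnames(m), c("A", "B"))
  expect_equal(matrix(m, nrow = 4), rbind(c(1, 0), c(0, 1), c(1, 1), c(0, 0)))
})

test_that("variance filter removes low-variance columns by population variance", {
  n <- 2000L
  rare <- c(1, rep(0, n - 1))            # p(1-p) ~ 0.0005 < 0.001
  balanced <- rep(c(0, 1), n / 2)        # variance 0.25
  constant <- rep(1, n)
  m <- cbind(rare = rare, balanced = balanced, constant = constant)
  out <- variance_filter(m)
  expect_identical(colnames(out), "balanced")
  # idempotent
  expect_identical(variance_filter(out), out)
  expect_error(variance_filter(m[0, , drop = FALSE]), "empty")
})

test_that("profile aggregation takes the elementwise median over replicates", {
  reps <- data.frame(key = c("a", "a", "a", "b", "b", "c"),
                     f1 = c(1, 3, 5, 1, 3, 9), f2 = c(2, 4, 100, 2, 4, 9))
  m <- aggregate_profiles(reps)
  expect_equal(unname(m["a", ]), c(3, 4))    # odd count: middle value
  expect_equal(unname(m["b", ]), c(2, 3))    # even count: midpoint
  expect_equal(unname(m["c", ]), c(9, 9))    # single replicate unchanged
  expect_error(aggregate_profiles(list(a = matrix(1, 1, 1, dimnames = list(NULL, "x")),
                                       b = matrix(1, 1, 1, dimnames = list(NULL, "y")))),
               "schema")
})

test_that("v-NN imputation uses strict-threshold neighbors and honors exclusions", {
  fp <- make_fp(list(q = 1:4, n1 = 1:5, n2 = c(1:4, 6), n3 = c(1:4, 7),
                     far = 8:9))
  prof <- matrix(c(1, 10, 2, 20, 3, 30), nrow = 3, byrow = TRUE,
                 dimnames = list(c("n1", "n2", "n3"), c("f1", "f2")))
  # all three neighbors at similarity 0.8 > 0.7: elementwise median
  expect_equal(unname(vnn_impute("q", fp, prof)), c(2, 20))
  # exclusion shrinks the pool
  expect_equal(unname(vnn_impute("q", fp, prof, excluded_keys = "n3")), c(1.5, 15))
  # single qualifying neighbor: verbatim profile
  expect_equal(unname(vnn_impute("q", fp, prof, excluded_keys = c("n2", "n3"))),
               c(1, 10))
  # no neighbor above threshold: dropped
  expect_null(vnn_impute("far", fp, prof))
  # strictness at the boundary: similarity == threshold is not enough
  expect_null(vnn_impute("q", fp, prof, sim_threshold = 0.8))
  # own profile returned verbatim
  expect_equal(unname(vnn_impute("n1", fp, prof)), c(1, 10))
  expect_error(vnn_impute("missing", fp, prof), "fingerprint")
  # imputed values lie within neighbor extremes (property)
  set.seed(42)
  for (i in 1:20) {
    bits <- lapply(1:6, function(j) sort(sample(1:12, 6)))
    names(bits) <- c("q", paste0("n", 1:5))
    f <- make_fp(bits)
    p <- matrix(rnorm(10), nrow = 5,
                dimnames = list(paste0("n", 1:5), c("x", "y")))
    v <- vnn_impute("q", f, p, sim_threshold = 0.3)
    if (!is.null(v)) {
      sims <- sapply(paste0("n", 1:5), function(k) tanimoto(f["q", ], f[k, ]))
      nb <- names(sims)[sims > 0.3]
      expect_true(all(v >= apply(p[nb, , drop = FALSE], 2, min) - 1e-12))
      expect_true(all(v <= apply(p[nb, , drop = FALSE], 2, max) + 1e-12))
    }
  }
})

test_that("raising the similarity threshold never enlarges the neighbor pool", {
  fp <- make_fp(list(q = 1:4, n1 = 1:5, n2 = c(1:4, 6), n3 = c(2:4, 7, 8)))
  prof <- matrix(1:6, nrow = 3, dimnames = list(c("n1", "n2", "n3"), c("a", "b")))
  pool_at <- function(th) {
    sims <- sapply(rownames(prof), function(k) tanimoto(fp["q", ], fp[k, ]))
    names(sims)[sims > th]
  }
  for (th in c(0.2, 0.5, 0.7, 0.9)) {
    expect_true(all(pool_at(th + 0.05) %in% pool_at(th)))
  }
})

test_that("log-scale Cmax features keep only positive values", {
  cm <- data.frame(key = c("a", "b", "c"), cmax_total = c(10, 0.1, NA),
                   cmax_unbound = c(1, 0.01, 2))
  ft <- cmax_feature(cm, "total")
  expect_identical(rownames(ft), c("a", "b"))
  expect_equal(unname(ft[, 1]), c(1, -1))
  fu <- cmax_feature(cm, "unbound")
  expect_identical(rownames(fu), c("a", "b", "c"))
})
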