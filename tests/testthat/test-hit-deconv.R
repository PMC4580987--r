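test_that("feature matching respects the ppm tolerance", {
  cmp <- make_campaign(n_alkynes = 6, rows = 2, cols = 3)
  plan <- plan_incubations(cmp$design, cmp$azides$id, "both")
  prod <- cmp$products
  # take one in-composition product and offset its m/z by known ppm errors
  inc <- plan[plan$condition == "enzyme", ][1, ]
  members <- attr(plan, "cluster_members")[[inc$cluster_label]]
  cand <- prod[prod$azide_id == inc$azide_id & prod$alkyne_id == members[1] &
                 prod$regio == "1,4", ]
  mk_feature <- function(ppm) data.frame(
    incubation_id = inc$incubation_id, condition = "enzyme",
    mz = cand$mz * (1 + ppm * 1e-6), rt_min = 5, intensity = 1000,
    stringsAsFactors = FALSE
  )
  m_in <- match_features(mk_feature(-0.94), prod, plan, ppm_tol = 5)
  expect_equal(nrow(m_in$assignments), 1)
  expect_equal(m_in$assignments$ppm_error, -0.94, tolerance = 1e-6)
  m_out <- match_features(mk_feature(49.9), prod, plan, ppm_tol = 5)
  expect_equal(nrow(m_out$assignments), 0)
  expect_equal(nrow(m_out$unmatched), 1)
  # property: assignments never exceed the tolerance under random noise
  set.seed(31)
  feats <- do.call(rbind, lapply(rnorm(40, 0, 6), mk_feature))
  m <- match_features(feats, prod, plan, ppm_tol = 5)
  expect_true(all(abs(m$assignments$ppm_error) <= 5))
  expect_equal(nrow(m$assignments) + nrow(m$unmatched), 40)
})

test_that("regioisomer mass ties are resolved by retention time", {
  cmp <- make_campaign(n_alkynes = 6, rows = 2, cols = 3)
  plan <- plan_incubations(cmp$design, cmp$azides$id, "both")
  prod <- cmp$products
  inc <- plan[plan$condition == "enzyme", ][1, ]
  members <- attr(plan, "cluster_members")[[inc$cluster_label]]
  pair <- prod[prod$azide_id == inc$azide_id & prod$alkyne_id == members[1], ]
  keys <- product_key(pair)
  rt_lib <- setNames(c(8.0, 9.5), keys)  # 1,4 at 8.0, 1,5 at 9.5
  feat <- data.frame(incubation_id = inc$incubation_id, condition = "enzyme",
                     mz = pair$mz[1], rt_min = 8.1, intensity = 1000,
                     stringsAsFactors = FALSE)
  m <- match_features(feat, prod, plan, ppm_tol = 5,
                      rt_library = rt_lib, rt_tol = 0.3)
  expect_equal(m$assignments$regio, "1,4")
  expect_equal(m$assignments$rt_error, 0.1, tolerance = 1e-9)
  # without an RT reference the assignment stays regio-ambiguous
  m2 <- match_features(feat, prod, plan, ppm_tol = 5)
  expect_equal(m2$assignments$regio, "?")
  # RT outside tolerance for both regios: also ambiguous
  feat$rt_min <- 12
  m3 <- match_features(feat, prod, plan, ppm_tol = 5,
                       rt_library = rt_lib, rt_tol = 0.3)
  expect_equal(m3$assignments$regio, "?")
})

test_that("hit calling enforces LOD and buffer enrichment", {
  cmp <- make_campaign(n_alkynes = 6, rows = 2, cols = 3)
  plan <- plan_incubations(cmp$design, cmp$azides$id, "x")
  prod <- cmp$products
  inc_e <- plan$incubation_id[plan$condition == "enzyme"][1]
  inc_b <- sub("enzyme$", "buffer", inc_e)
  members <- attr(plan, "cluster_members")[[plan$cluster_label[plan$incubation_id == inc_e]]]
  az <- plan$azide_id[plan$incubation_id == inc_e]
  p <- prod[prod$azide_id == az & prod$alkyne_id %in% members[1:3] &
              prod$regio == "1,4", ]
  feat <- data.frame(
    incubation_id = c(inc_e, inc_e, inc_b, inc_e),
    condition = c("enzyme", "enzyme", "buffer", "enzyme"),
    mz = c(p$mz[1], p$mz[2], p$mz[2], p$mz[3]),
    rt_min = 5,
    intensity = c(900, 300, 290, 90),
    stringsAsFactors = FALSE
  )
  m <- match_features(feat, prod, plan, ppm_tol = 5)
  hits <- call_hits(m$assignments, plan, lod = 100, enrichment_threshold = 3)
  h1 <- hits[hits$alkyne_id == p$alkyne_id[1], ]
  expect_true(h1$is_hit)           # 900 vs absent buffer: ratio Inf
  expect_equal(h1$enrichment_ratio, Inf)
  h2 <- hits[hits$alkyne_id == p$alkyne_id[2], ]
  expect_false(h2$is_hit)          # 300/290 ~ 1.03 < 3
  expect_equal(h2$enrichment_ratio, 300 / 290, tolerance = 1e-12)
  h3 <- hits[hits$alkyne_id == p$alkyne_id[3], ]
  expect_false(h3$is_hit)          # below LOD
})

test_that("missing buffer partners are rejected by name", {
  cmp <- make_campaign(n_alkynes = 6, rows = 2, cols = 3)
  plan <- plan_incubations(cmp$design, cmp$azides$id, "x")
  plan_broken <- plan[!(plan$condition == "buffer" & plan$cluster_label == "X_1"), ]
  attr(plan_broken, "cluster_members") <- attr(plan, "cluster_members")
  a <- data.frame(incubation_id = character(0), condition = character(0),
                  mz = numeric(0), rt_min = numeric(0), intensity = numeric(0),
                  azide_id = character(0), alkyne_id = character(0),
                  regio = character(0), product_key = character(0),
                  ppm_error = numeric(0), rt_error = numeric(0),
                  tie_flag = logical(0))
  expect_error(call_hits(a, plan_broken), "without a buffer partner.*X_1")
})

test_that("intersection mode needs both pool contexts; either mode one", {
  cmp <- make_campaign()
  plan <- plan_incubations(cmp$design, cmp$azides$id, "both")
  bs <- data.frame(azide_id = "AZ1", alkyne_id = "ALK13")
  cfg <- tgs_config(seed = 8, binder_set = bs, ppm_sigma = 0,
                    intensity_cv = 0, rt_jitter = 0)
  sim <- simulate_tgs(plan, cmp$products, cfg)
  m <- match_features(sim$features, cmp$products, plan,
                      rt_library = sim$truth$rt_library)
  hits <- call_hits(m$assignments, plan)
  # full evidence: confirmed in intersection mode with X and Y context
  rep_i <- consensus_deconvolution(hits, cmp$design, "intersection", truth = bs)
  expect_equal(rep_i$precision, 1)
  expect_equal(rep_i$recall, 1)
  expect_match(rep_i$confirmed$x_clusters, "^X_")
  expect_match(rep_i$confirmed$y_clusters, "^Y_")
  # drop the Y-context hits: intersection no longer confirms, either does
  hits_x <- hits[grepl("^X_", hits$cluster_label), ]
  rep_x_i <- consensus_deconvolution(hits_x, cmp$design, "intersection", truth = bs)
  expect_equal(nrow(rep_x_i$confirmed), 0)
  rep_x_e <- consensus_deconvolution(hits_x, cmp$design, "either", truth = bs)
  expect_equal(rep_x_e$recall, 1)
  # unknown cluster labels are rejected
  hits_bad <- hits; hits_bad$cluster_label[1] <- "X_99"
  expect_error(consensus_deconvolution(hits_bad, cmp$design), "absent from design")
})

test_that("noiseless campaigns are recovered exactly across random binder sets", {
  cmp <- make_campaign()
  plan <- plan_incubations(cmp$design, cmp$azides$id, "both")
  for (seed in 1:25) {
    set.seed(seed)
    bs <- sample_binder_set(cmp$lib, sample(1:10, 1))
    cfg <- tgs_config(seed = seed, binder_set = bs, ppm_sigma = 0,
                      intensity_cv = 0, rt_jitter = 0)
    sim <- simulate_tgs(plan, cmp$products, cfg)
    m <- match_features(sim$features, cmp$products, plan,
                        rt_library = sim$truth$rt_library)
    hits <- call_hits(m$assignments, plan)
    rep <- consensus_deconvolution(hits, cmp$design, "intersection", truth = bs)
    expect_equal(rep$precision, 1)
    expect_equal(rep$recall, 1)
  }
})

test_that("raising the enrichment threshold never grows the confirmed set", {
  cmp <- make_campaign()
  plan <- plan_incubations(cmp$design, cmp$azides$id, "both")
  set.seed(41); bs <- sample_binder_set(cmp$lib, 6)
  cfg <- tgs_config(seed = 41, binder_set = bs)
  sim <- simulate_tgs(plan, cmp$products, cfg)
  m <- match_features(sim$features, cmp$products, plan,
                      rt_library = sim$truth$rt_library)
  sizes <- vapply(c(1, 3, 10, 100, Inf), function(th) {
    hits <- call_hits(m$assignments, plan, enrichment_threshold = th)
    nrow(consensus_deconvolution(hits, cmp$design)$confirmed)
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("SAR summary computes per-tag fold enrichment", {
  # toy library: 2 azides (one naphthyl), binders all from the naphthyl one
  reag <- reagent_table(
    id = c("A1", "A2", "K1", "K2", "K3", "K4"),
    role = c("azide", "azide", rep("alkyne", 4)),
    formula = c("C10H11N5O2", "C9H9N5O2", "C5H8", "C6H10", "C7H12", "C8H14"),
    sar_tags = list("naphthyl", "phenyl", c("amide_linker"), c("amide_linker"),
                    c("sulfonamide_linker"), c("ether_linker"))
  )
  rep <- list(confirmed = data.frame(
    azide_id = c("A1", "A1"), alkyne_id = c("K1", "K2"),
    stringsAsFactors = FALSE
  ))
  s <- sar_summary(rep, reag)
  naph <- s[s$tag == "naphthyl", ]
  expect_equal(naph$fold_enrichment, 1.0 / 0.5)  # all binders naphthyl, 50% base
  amide <- s[s$tag == "amide_linker", ]
  expect_equal(amide$hit_rate, 1.0)
  expect_equal(amide$base_rate, 0.5)
  expect_equal(amide$fold_enrichment, 2.0)
  ether <- s[s$tag == "ether_linker", ]
  expect_equal(ether$hit_rate, 0)
  # empty binder set: base rates only, zero hit rates
  s0 <- sar_summary(list(confirmed = data.frame(azide_id = character(0),
                                                alkyne_id = character(0))),
                    reag)
  expect_true(all(s0$hit_rate == 0))
  expect_true(all(s0$n_binders_with_tag == 0))
})

test_that("noisy campaigns keep high recall at default thresholds", {
  cmp <- make_campaign()
  plan <- plan_incubations(cmp$design, cmp$azides$id, "both")
  recalls <- vapply(1:30, function(seed) {
    set.seed(seed + 1000)
    bs <- sample_binder_set(cmp$lib, sample(1:10, 1))
    cfg <- tgs_config(seed = seed, binder_set = bs,
                      ppm_sigma = 2, intensity_cv = 0.3)
    sim <- simulate_tgs(plan, cmp$products, cfg)
    m <- match_features(sim$features, cmp$products, plan,
                        rt_library = sim$truth$rt_library)
    hits <- call_hits(m$assignments, plan)
    consensus_deconvolution(hits, cmp$design, "intersection", truth = bs)$recall
  }, numeric(1))
  expect_gte(mean(recalls), 0.95)
})
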