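#' Configuration for the templated-synthesis simulator
#'
#' The simulator abstracts in-situ click kinetics to a two-level amount
#' model: every azide/alkyne pair present in an incubation forms its
#' triazole at a background level `k_bg`, and in the enzyme condition
#' the pairs in `binder_set` are boosted by `templation_factor`
#' (applied to both regioisomers, since templating accelerates 1,4 and
#' 1,5 formation to comparable extents). Observations then receive
#' multiplicative lognormal intensity noise, Gaussian ppm mass error
#' and Gaussian retention-time jitter, and rows below the detection
#' limit are suppressed.
#'
#' @param seed integer; fixes all randomness of a simulation.
#' @param k_bg background product amount (arbitrary intensity units).
#' @param templation_factor multiplicative boost (> 1) for binders in
#'   enzyme incubations.
#' @param binder_set data.frame with columns `azide_id, alkyne_id` and
#'   optionally `regio` (absent regio means both regioisomers).
#' @param enzyme_conc enzyme concentration, uM (metadata only).
#' @param reagent_conc per-component reagent concentration, mM
#'   (metadata only).
#' @param ppm_sigma mass-noise s.d. in ppm.
#' @param rt_jitter retention-time jitter s.d., min.
#' @param lod intensity detection limit.
#' @param intensity_cv lognormal coefficient of variation of intensity.
#' @param competition when `TRUE`, the total templated excess per
#'   mixture is a fixed budget `k_bg * (templation_factor - 1)` shared
#'   equally among the binder products present.
#' @return list of class `tgs_config`.
#' @export
tgs_config <- function(seed = 1L,
                       k_bg = 100,
                       templation_factor = 20,
                       binder_set = NULL,
                       enzyme_conc = 4.8,
                       reagent_conc = 0.1,
                       ppm_sigma = 2,
                       rt_jitter = 0.05,
                       lod = 250,
                       intensity_cv = 0.3,
                       competition = FALSE) {
  if (templation_factor <= 1) stop("templation_factor must exceed 1")
  if (ppm_sigma < 0 || lod < 0 || intensity_cv < 0 || rt_jitter < 0) {
    stop("noise parameters and lod must be non-negative")
  }
  if (!is.null(binder_set)) {
    if (!all(c("azide_id", "alkyne_id") %in% names(binder_set))) {
      stop("binder_set needs columns azide_id, alkyne_id")
    }
  }
  structure(
    list(seed = as.integer(seed), k_bg = k_bg,
         templation_factor = templation_factor, binder_set = binder_set,
         enzyme_conc = enzyme_conc, reagent_conc = reagent_conc,
         ppm_sigma = ppm_sigma, rt_jitter = rt_jitter, lod = lod,
         intensity_cv = intensity_cv, competition = competition),
    class = "tgs_config"
  )
}

#' Draw a random ground-truth binder set
#'
#' Mirrors the qualitative SAR of the screen being emulated: binders
#' come from the naphthyl azide and are enriched for amide- and
#' sulfonamide-linker alkynes.
#'
#' @param reagents a `reagent_table`.
#' @param n_binders number of binder pairs.
#' @param azide_tag tag selecting the productive azide (default
#'   `"naphthyl"`; falls back to the first azide if no tag matches).
#' @param favored_tags alkyne tags whose holders are 4x more likely to
#'   be drawn.
#' @return data.frame `azide_id, alkyne_id` (regio-agnostic: both
#'   regioisomers of each pair are templated).
#' @export
sample_binder_set <- function(reagents, n_binders,
                              azide_tag = "naphthyl",
                              favored_tags = c("amide_linker", "sulfonamide_linker")) {
  tags <- sar_tag_list(reagents)
  azides <- reagents$id[reagents$role == "azide"]
  tagged <- azides[vapply(tags[azides], function(t) azide_tag %in% t, logical(1))]
  azide <- if (length(tagged) > 0) tagged[1] else azides[1]
  alkynes <- reagents$id[reagents$role == "alkyne"]
  if (n_binders > length(alkynes)) stop("n_binders exceeds alkyne count")
  w <- vapply(tags[alkynes], function(t) {
    if (any(favored_tags %in% t)) 4 else 1
  }, numeric(1))
  chosen <- sample(alkynes, n_binders, prob = w)
  data.frame(azide_id = rep(azide, n_binders), alkyne_id = chosen,
             stringsAsFactors = FALSE)
}

#' Plan pooled incubations over a design
#'
#' One enzyme and one buffer incubation per (azide, cluster) in the
#' selected partition(s). Running only the 10-cluster Y partition of a
#' 9 x 10 design against 2 azides gives the campaign's 20 reagent
#' mixtures (40 incubations with their buffer controls); both
#' partitions give 19 x 2 mixtures (76 incubations).
#'
#' @param design a `pooling_design`.
#' @param azide_ids character vector of azide ids.
#' @param partitions `"x"`, `"y"`, or `"both"`.
#' @return data.frame of class `incubation_plan` with columns
#'   `incubation_id, azide_id, cluster_label, condition` plus the
#'   attribute `cluster_members` (named list of alkyne id vectors).
#' @export
plan_incubations <- function(design, azide_ids, partitions = c("both", "x", "y")) {
  partitions <- match.arg(partitions)
  clusters <- switch(partitions,
    x = design$partition_x,
    y = design$partition_y,
    both = c(design$partition_x, design$partition_y)
  )
  azide_ids <- as.character(azide_ids)
  if (length(azide_ids) == 0 || length(clusters) == 0) {
    out <- data.frame(incubation_id = character(0), azide_id = character(0),
                      cluster_label = character(0), condition = character(0),
                      stringsAsFactors = FALSE)
    attr(out, "cluster_members") <- clusters
    class(out) <- c("incubation_plan", "data.frame")
    return(out)
  }
  grid <- expand.grid(condition = c("enzyme", "buffer"),
                      cluster_label = names(clusters), azide_id = azide_ids,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- data.frame(
    incubation_id = paste(grid$azide_id, grid$cluster_label, grid$condition,
                          sep = "."),
    azide_id = grid$azide_id,
    cluster_label = grid$cluster_label,
    condition = grid$condition,
    stringsAsFactors = FALSE
  )
  attr(out, "cluster_members") <- clusters
  class(out) <- c("incubation_plan", "data.frame")
  out
}

#' Simulate LC-MS feature tables for a pooled campaign
#'
#' For each planned incubation, every product of the azide with an
#' alkyne of that cluster can form. Expected amounts follow the
#' two-level model of [tgs_config()]; observations get lognormal
#' intensity noise, ppm-scaled Gaussian m/z error and Gaussian RT
#' jitter, and rows below `lod` are dropped. A retention-time library
#' (one U(1, 20)-min draw per product; regioisomers co-mass but get
#' distinct RTs, as they separate chromatographically) is drawn once at
#' simulation start. Identical seeds give identical tables.
#'
#' @param plan an `incubation_plan`.
#' @param products a `product_library`.
#' @param cfg a `tgs_config`.
#' @return list of class `tgs_simulation`:
#'   `features` (data.frame `incubation_id, condition, mz, rt_min,
#'   intensity`), and `truth` (list with `binder_set`, `rt_library`,
#'   `amounts` — the noiseless per-incubation expected amounts).
#' @export
simulate_tgs <- function(plan, products, cfg) {
  stopifnot(inherits(cfg, "tgs_config"))
  clusters <- attr(plan, "cluster_members")
  set.seed(cfg$seed)
  keys <- product_key(products)
  rt_library <- stats::setNames(stats::runif(nrow(products), 1, 20), keys)

  binder_keys <- character(0)
  if (!is.null(cfg$binder_set) && nrow(cfg$binder_set) > 0) {
    bs <- cfg$binder_set
    if (is.null(bs$regio)) {
      bs <- merge(bs, data.frame(regio = c("1,4", "1,5")))
    }
    binder_keys <- paste(bs$azide_id, bs$alkyne_id, bs$regio, sep = "|")
    missing <- setdiff(binder_keys, keys)
    if (length(missing) > 0) {
      stop("binder_set references unknown product(s): ",
           paste(missing, collapse = ", "))
    }
  }

  rows <- vector("list", nrow(plan))
  for (r in seq_len(nrow(plan))) {
    members <- clusters[[plan$cluster_label[r]]]
    idx <- which(products$azide_id == plan$azide_id[r] &
                   products$alkyne_id %in% members)
    if (length(idx) == 0) next
    k <- keys[idx]
    templated <- plan$condition[r] == "enzyme" & k %in% binder_keys
    amount <- rep(cfg$k_bg, length(idx))
    if (any(templated)) {
      if (cfg$competition) {
        budget <- cfg$k_bg * (cfg$templation_factor - 1)
        amount[templated] <- cfg$k_bg + budget / sum(templated)
      } else {
        amount[templated] <- cfg$k_bg * cfg$templation_factor
      }
    }
    rows[[r]] <- data.frame(
      incubation_id = plan$incubation_id[r],
      condition = plan$condition[r],
      product_key = k,
      amount = amount,
      mz_true = products$mz[idx],
      rt_true = rt_library[k],
      stringsAsFactors = FALSE
    )
  }
  truth_amounts <- do.call(rbind, rows)
  if (is.null(truth_amounts)) {
    truth_amounts <- data.frame(incubation_id = character(0),
                                condition = character(0),
                                product_key = character(0), amount = numeric(0),
                                mz_true = numeric(0), rt_true = numeric(0))
  }
  rownames(truth_amounts) <- NULL

  n <- nrow(truth_amounts)
  if (n > 0) {
    if (cfg$intensity_cv > 0) {
      sdlog <- sqrt(log(1 + cfg$intensity_cv^2))
      noise <- stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else {
      noise <- rep(1, n)
    }
    intensity <- truth_amounts$amount * noise
    mz <- truth_amounts$mz_true *
      (1 + stats::rnorm(n, 0, cfg$ppm_sigma) * 1e-6)
    rt <- truth_amounts$rt_true + stats::rnorm(n, 0, cfg$rt_jitter)
  } else {
    intensity <- mz <- rt <- numeric(0)
  }
  keep <- intensity >= cfg$lod
  features <- data.frame(
    incubation_id = truth_amounts$incubation_id[keep],
    condition = truth_amounts$condition[keep],
    mz = mz[keep], rt_min = rt[keep], intensity = intensity[keep],
    stringsAsFactors = FALSE
  )
  features <- features[order(features$incubation_id, features$mz), ]
  rownames(features) <- NULL
  structure(
    list(features = features,
         truth = list(binder_set = cfg$binder_set,
                      binder_keys = binder_keys,
                      rt_library = rt_library,
                      amounts = truth_amounts)),
    class = "tgs_simulation"
  )
}

#' Write a feature table CSV (`incubation_id,condition,mz,rt_min,intensity`)
#' @param features feature data.frame from [simulate_tgs()].
#' @param path output CSV path.
#' @export
write_features <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature table CSV
#' @param path CSV with columns `incubation_id,condition,mz,rt_min,intensity`.
#' @return feature data.frame.
#' @export
read_features <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
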