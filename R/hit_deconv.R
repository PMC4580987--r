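#' Match LC-MS features to the theoretical product library
#'
#' Each feature is compared only against products whose reagents were
#' actually present in its incubation (the mixture compositions are
#' known by design), and assigned to the candidate with the smallest
#' absolute ppm error within `ppm_tol`. Regioisomers share an exact
#' mass; when a retention-time reference is available the nearest RT
#' within `rt_tol` resolves the regiochemistry, otherwise the
#' assignment is kept regio-ambiguous (`regio = "?"`). Mass ties
#' between different pairs are broken towards the higher library mass
#' index and flagged.
#'
#' @param features data.frame `incubation_id, condition, mz, rt_min,
#'   intensity` (as written by [simulate_tgs()]).
#' @param products a `product_library`.
#' @param plan the `incubation_plan` the features came from.
#' @param ppm_tol mass tolerance in ppm (> 0), default 5.
#' @param rt_library optional named numeric (product key -> RT, min).
#' @param rt_tol RT tolerance in min for regio disambiguation.
#' @return list with `assignments` (one row per matched feature:
#'   feature columns plus `azide_id, alkyne_id, regio, product_key,
#'   ppm_error, rt_error, tie_flag`) and `unmatched` (feature rows with
#'   no candidate within tolerance).
#' @export
match_features <- function(features, products, plan, ppm_tol = 5,
                           rt_library = NULL, rt_tol = 0.3) {
  if (ppm_tol <= 0) stop("ppm_tol must be positive")
  clusters <- attr(plan, "cluster_members")
  keys <- product_key(products)
  assigned <- vector("list", nrow(features))
  unmatched <- logical(nrow(features))
  plan_row <- match(features$incubation_id, plan$incubation_id)
  if (anyNA(plan_row)) {
    stop("feature(s) reference incubations absent from the plan: ",
         paste(unique(features$incubation_id[is.na(plan_row)]), collapse = ", "))
  }
  # candidate product indices per incubation, computed once
  cand_by_inc <- lapply(seq_len(nrow(plan)), function(r) {
    members <- clusters[[plan$cluster_label[r]]]
    which(products$azide_id == plan$azide_id[r] &
            products$alkyne_id %in% members)
  })
  for (f in seq_len(nrow(features))) {
    cand <- cand_by_inc[[plan_row[f]]]
    if (length(cand) == 0) { unmatched[f] <- TRUE; next }
    ppm <- (features$mz[f] - products$mz[cand]) / products$mz[cand] * 1e6
    ok <- abs(ppm) <= ppm_tol
    if (!any(ok)) { unmatched[f] <- TRUE; next }
    cand <- cand[ok]; ppm <- ppm[ok]
    best <- abs(ppm) <= min(abs(ppm)) + 1e-9
    cand <- cand[best]; ppm <- ppm[best]
    tie_flag <- FALSE
    rt_error <- NA_real_
    if (length(cand) > 1) {
      pairs <- unique(paste(products$azide_id[cand], products$alkyne_id[cand]))
      if (length(pairs) > 1) {
        # distinct pairs tied on mass: deterministic break, flagged
        pick <- which.max(cand)
        cand <- cand[pick]; ppm <- ppm[pick]
        tie_flag <- TRUE
      }
    }
    regio <- products$regio[cand][1]
    if (length(cand) > 1) {
      # regioisomers of one pair: resolve by RT if a reference exists
      if (!is.null(rt_library)) {
        drt <- abs(features$rt_min[f] - rt_library[keys[cand]])
        if (any(drt <= rt_tol, na.rm = TRUE)) {
          pick <- which.min(drt)
          rt_error <- features$rt_min[f] - rt_library[keys[cand]][[pick]]
          regio <- products$regio[cand[pick]]
          ppm <- ppm[pick]; cand <- cand[pick]
        } else {
          regio <- "?"; ppm <- ppm[1]; cand <- cand[1]
        }
      } else {
        regio <- "?"; ppm <- ppm[1]; cand <- cand[1]
      }
    } else if (!is.null(rt_library)) {
      rt_error <- features$rt_min[f] - rt_library[[keys[cand]]]
    }
    assigned[[f]] <- data.frame(
      features[f, , drop = FALSE],
      azide_id = products$azide_id[cand], alkyne_id = products$alkyne_id[cand],
      regio = regio,
      product_key = paste(products$azide_id[cand], products$alkyne_id[cand],
                          regio, sep = "|"),
      ppm_error = ppm, rt_error = rt_error, tie_flag = tie_flag,
      stringsAsFactors = FALSE
    )
  }
  out_a <- do.call(rbind, assigned[!unmatched & !vapply(assigned, is.null, logical(1))])
  if (is.null(out_a)) {
    out_a <- data.frame(incubation_id = character(0), condition = character(0),
                        mz = numeric(0), rt_min = numeric(0),
                        intensity = numeric(0), azide_id = character(0),
                        alkyne_id = character(0), regio = character(0),
                        product_key = character(0), ppm_error = numeric(0),
                        rt_error = numeric(0), tie_flag = logical(0),
                        stringsAsFactors = FALSE)
  }
  rownames(out_a) <- NULL
  list(assignments = out_a, unmatched = features[unmatched, , drop = FALSE])
}

#' Call templated hits against buffer controls
#'
#' Enzyme and buffer incubations are paired by (azide, cluster). A
#' product is a hit when its enzyme-condition intensity reaches the
#' detection limit and its enzyme/buffer enrichment ratio reaches the
#' threshold (ratio is `Inf` when the product is absent from the buffer
#' control; products seen only in buffer are never hits). Use
#' `enrichment_threshold = Inf` for strict presence/absence calling.
#'
#' @param assignments the `assignments` data.frame from
#'   [match_features()].
#' @param plan the `incubation_plan`.
#' @param lod intensity detection limit.
#' @param enrichment_threshold minimum enzyme/buffer intensity ratio,
#'   default 3.
#' @return data.frame of hit calls: `azide_id, cluster_label,
#'   product_key, alkyne_id, regio, enzyme_intensity, buffer_intensity,
#'   enrichment_ratio, is_hit`.
#' @export
call_hits <- function(assignments, plan, lod = 250, enrichment_threshold = 3) {
  enz <- plan[plan$condition == "enzyme", ]
  buf <- plan[plan$condition == "buffer", ]
  pairkey <- function(df) paste(df$azide_id, df$cluster_label, sep = "|")
  missing_buf <- setdiff(pairkey(enz), pairkey(buf))
  if (length(missing_buf) > 0) {
    stop("enzyme incubation(s) without a buffer partner: ",
         paste(missing_buf, collapse = ", "))
  }
  if (nrow(assignments) == 0) {
    return(data.frame(azide_id = character(0), cluster_label = character(0),
                      product_key = character(0), alkyne_id = character(0),
                      regio = character(0), enzyme_intensity = numeric(0),
                      buffer_intensity = numeric(0),
                      enrichment_ratio = numeric(0), is_hit = logical(0),
                      stringsAsFactors = FALSE))
  }
  a <- assignments
  a$cluster_label <- plan$cluster_label[match(a$incubation_id, plan$incubation_id)]
  grp <- paste(a$azide_id, a$cluster_label, a$product_key, sep = "\r")
  agg <- function(cond) {
    sel <- a$condition == cond
    tapply(a$intensity[sel], grp[sel], sum)
  }
  e_int <- agg("enzyme"); b_int <- agg("buffer")
  all_grp <- union(names(e_int), names(b_int))
  parts <- strsplit(all_grp, "\r", fixed = TRUE)
  enzyme_intensity <- ifelse(all_grp %in% names(e_int), e_int[all_grp], 0)
  buffer_intensity <- ifelse(all_grp %in% names(b_int), b_int[all_grp], 0)
  ratio <- ifelse(buffer_intensity > 0, enzyme_intensity / buffer_intensity, Inf)
  pk <- vapply(parts, `[`, character(1), 3)
  pk_parts <- strsplit(pk, "|", fixed = TRUE)
  out <- data.frame(
    azide_id = vapply(parts, `[`, character(1), 1),
    cluster_label = vapply(parts, `[`, character(1), 2),
    product_key = pk,
    alkyne_id = vapply(pk_parts, `[`, character(1), 2),
    regio = vapply(pk_parts, `[`, character(1), 3),
    enzyme_intensity = as.numeric(enzyme_intensity),
    buffer_intensity = as.numeric(buffer_intensity),
    enrichment_ratio = as.numeric(ratio),
    stringsAsFactors = FALSE
  )
  out$is_hit <- out$enzyme_intensity >= lod & out$enrichment_ratio >= enrichment_threshold
  out <- out[order(out$azide_id, out$cluster_label, out$product_key), ]
  rownames(out) <- NULL
  out
}

#' Deconvolute binder identities from pooled hit calls
#'
#' The orthogonal design places each alkyne in exactly one X pool and
#' one Y pool. In `"intersection"` mode a pair is confirmed only when
#' it is called a hit in both its X-pool context and its Y-pool context
#' for the same azide; `"either"` mode confirms on one context.
#' Confirmation is at the (azide, alkyne) pair level — the two
#' regioisomers co-mass and count as evidence for the same pair — with
#' the regiochemistries seen recorded as evidence.
#'
#' @param hits data.frame from [call_hits()].
#' @param design the `pooling_design`.
#' @param mode `"intersection"` (default) or `"either"`.
#' @param truth optional ground-truth binder set (data.frame
#'   `azide_id, alkyne_id`) for precision/recall.
#' @return list of class `binder_report`: `confirmed` (data.frame
#'   `azide_id, alkyne_id, x_clusters, y_clusters, regios`),
#'   `ambiguous_regio` (pairs only ever seen regio-ambiguous),
#'   `n_hits`, and when truth is given `precision`, `recall`.
#' @export
consensus_deconvolution <- function(hits, design, mode = c("intersection", "either"),
                                    truth = NULL) {
  mode <- match.arg(mode)
  known <- c(names(design$partition_x), names(design$partition_y))
  bad <- setdiff(unique(hits$cluster_label), known)
  if (length(bad) > 0) {
    stop("hit cluster label(s) absent from design: ", paste(bad, collapse = ", "))
  }
  h <- hits[hits$is_hit, , drop = FALSE]
  pair <- paste(h$azide_id, h$alkyne_id, sep = "|")
  axis <- ifelse(h$cluster_label %in% names(design$partition_x), "x", "y")
  confirmed <- data.frame(azide_id = character(0), alkyne_id = character(0),
                          x_clusters = character(0), y_clusters = character(0),
                          regios = character(0), stringsAsFactors = FALSE)
  ambiguous <- character(0)
  for (p in unique(pair)) {
    sel <- pair == p
    xs <- unique(h$cluster_label[sel & axis == "x"])
    ys <- unique(h$cluster_label[sel & axis == "y"])
    ok <- if (mode == "intersection") length(xs) > 0 && length(ys) > 0
          else length(xs) > 0 || length(ys) > 0
    if (!ok) next
    regios <- unique(h$regio[sel])
    if (all(regios == "?")) ambiguous <- c(ambiguous, p)
    ids <- strsplit(p, "|", fixed = TRUE)[[1]]
    confirmed <- rbind(confirmed, data.frame(
      azide_id = ids[1], alkyne_id = ids[2],
      x_clusters = paste(xs, collapse = ";"),
      y_clusters = paste(ys, collapse = ";"),
      regios = paste(sort(regios), collapse = ";"),
      stringsAsFactors = FALSE
    ))
  }
  rownames(confirmed) <- NULL
  out <- list(confirmed = confirmed, ambiguous_regio = ambiguous,
              n_hits = nrow(h), mode = mode)
  if (!is.null(truth)) {
    truth_pairs <- unique(paste(truth$azide_id, truth$alkyne_id, sep = "|"))
    found <- unique(paste(confirmed$azide_id, confirmed$alkyne_id, sep = "|"))
    tp <- length(intersect(found, truth_pairs))
    out$precision <- if (length(found) > 0) tp / length(found) else NA_real_
    out$recall <- if (length(truth_pairs) > 0) tp / length(truth_pairs) else NA_real_
  }
  class(out) <- "binder_report"
  out
}

#' @export
print.binder_report <- function(x, ...) {
  cat("<binder_report> ", nrow(x$confirmed), " confirmed pair(s) from ",
      x$n_hits, " hit call(s) [mode=", x$mode, "]\n", sep = "")
  if (!is.null(x$precision)) {
    cat("  precision=", format(x$precision, digits = 3),
        " recall=", format(x$recall, digits = 3), "\n", sep = "")
  }
  invisible(x)
}

#' Summarize structure-activity enrichment of SAR tags among binders
#'
#' For every SAR tag, compares its frequency among the confirmed
#' binders' reagents (per role) with its base frequency in the library:
#' `fold_enrichment = hit_rate / base_rate`. An amide/sulfonamide
#' linker preference or a single productive warhead shows up as fold
#' enrichment > 1.
#'
#' @param report a `binder_report`.
#' @param reagents the `reagent_table` of the campaign.
#' @return data.frame `role, tag, n_binders_with_tag,
#'   n_library_with_tag, hit_rate, base_rate, fold_enrichment`
#'   (fold is `NA` when the base rate is 0).
#' @export
sar_summary <- function(report, reagents) {
  tags <- sar_tag_list(reagents)
  rows <- list()
  for (role in c("azide", "alkyne")) {
    lib_ids <- reagents$id[reagents$role == role]
    n_lib <- length(lib_ids)
    binder_ids <- if (role == "azide") report$confirmed$azide_id else report$confirmed$alkyne_id
    binder_ids <- unique(binder_ids)
    n_bind <- length(binder_ids)
    role_tags <- sort(unique(unlist(tags[lib_ids])))
    for (tg in role_tags) {
      has <- vapply(tags[lib_ids], function(t) tg %in% t, logical(1))
      n_library_with_tag <- sum(has)
      n_binders_with_tag <- sum(vapply(tags[binder_ids], function(t) tg %in% t,
                                       logical(1)))
      hit_rate <- if (n_bind > 0) n_binders_with_tag / n_bind else 0
      base_rate <- n_library_with_tag / n_lib
      rows[[length(rows) + 1L]] <- data.frame(
        role = role, tag = tg,
        n_binders_with_tag = n_binders_with_tag,
        n_library_with_tag = n_library_with_tag,
        hit_rate = hit_rate, base_rate = base_rate,
        fold_enrichment = if (base_rate > 0) hit_rate / base_rate else NA_real_,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
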