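# Overrepresentation of smoking-associated CpGs in curated EWAS catalog CpG
# sets: Fisher exact (hypergeometric) overlap tests and a pre-ranked
# running-sum enrichment score with permutation-normalized NES.

#' Filter an EWAS catalog of per-association records
#'
#' Keeps associations passing the array-specific Bonferroni threshold
#' (`alpha / array size`; strict <) with population size strictly above
#' `n_min`, then rebuilds sets, dropping any left empty.
#'
#' @param assoc data.frame with columns `set`, `trait`, `cpg_id`, `p`,
#'   `array` (one of `names(array_sizes)`), `n`.
#' @param n_min minimum population size (strict >).
#' @param alpha numerator of the per-array Bonferroni rule.
#' @param array_sizes named vector of probe counts per array.
#' @return named list of sets: `list(name, trait, ids)`.
#' @export
filter_catalog <- function(assoc, n_min = 100, alpha = 0.05,
                           array_sizes = c("450k" = 450000,
                                           "EPIC" = 850000)) {
  unknown <- setdiff(unique(assoc$array), names(array_sizes))
  if (length(unknown) > 0) {
    stop("unknown array label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  thr <- alpha / array_sizes[assoc$array]
  keep <- assoc$p < thr & assoc$n > n_min
  assoc <- assoc[keep, , drop = FALSE]
  sets <- lapply(split(assoc, assoc$set), function(d) {
    list(name = d$set[1], trait = d$trait[1], ids = unique(d$cpg_id))
  })
  sets[vapply(sets, function(s) length(s$ids) > 0, TRUE)]
}

#' Fisher exact overlap of a query CpG set with a catalog set
#'
#' One-sided (enrichment) hypergeometric upper-tail p from the 2x2 partition
#' of the universe; odds ratio with Haldane correction (+0.5 per cell) when
#' any cell is zero. Ids outside the universe are dropped with a warning.
#'
#' @param query character vector of CpG ids (e.g. the smCpGs).
#' @param target catalog set ids.
#' @param universe all tested CpG ids.
#' @return list with `overlap`, `odds_ratio`, `p`.
#' @export
fisher_overlap <- function(query, target, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  n_out <- sum(!query %in% universe) + sum(!target %in% universe)
  if (n_out > 0) warning(n_out, " id(s) outside the universe dropped")
  q <- unique(intersect(query, universe))
  t <- unique(intersect(target, universe))
  k <- length(intersect(q, t))
  a <- k
  b <- length(q) - k
  c_ <- length(t) - k
  d <- length(universe) - length(q) - length(t) + k
  p <- stats::phyper(k - 1, length(t), length(universe) - length(t),
                     length(q), lower.tail = FALSE)
  cells <- c(a, b, c_, d)
  if (any(cells == 0)) cells <- cells + 0.5
  list(overlap = k,
       odds_ratio = (cells[1] * cells[4]) / (cells[2] * cells[3]),
       p = p)
}

# running-sum enrichment score of `target` in the ranking defined by
# `scores` (descending). Hits increment by |score|^exponent / sum over
# hits; misses decrement by 1/(N - n_target). ES is the signed extremum.
running_es <- function(ord_scores, is_hit, exponent) {
  n <- length(ord_scores)
  n_hit <- sum(is_hit)
  w <- abs(ord_scores)^exponent
  inc <- numeric(n)
  denom_hit <- sum(w[is_hit])
  if (denom_hit == 0) {
    inc[is_hit] <- 1 / n_hit  # all-zero scores: unweighted steps
  } else {
    inc[is_hit] <- w[is_hit] / denom_hit
  }
  inc[!is_hit] <- -1 / (n - n_hit)
  rs <- cumsum(inc)
  rs[which.max(abs(rs))]
}

#' Pre-ranked enrichment score with permutation NES
#'
#' Orders the universe by score (descending), computes the weighted
#' running-sum enrichment score of the target set, and normalizes against
#' `n_perm` random sets of the same size drawn from the universe
#' (set-membership permutation): NES = ES / mean(|permuted ES| of the same
#' sign). Deterministic under `seed`.
#'
#' @param scores named numeric vector: per-CpG ranking score over the
#'   universe (e.g. -log10 of the minimum EWAS p across cell types).
#' @param target CpG ids of the set to test.
#' @param weight_exponent exponent on |score| for hit increments (0 =
#'   unweighted / classical Kolmogorov-Smirnov form).
#' @param n_perm number of permutations.
#' @param seed integer seed (required).
#' @return list with `es`, `nes`, `p_perm` (one-sided permutation p for the
#'   observed sign), `n_hits`, `perm_es` (the permuted scores, reusable for
#'   collection-level FDR).
#' @export
preranked_es <- function(scores, target, weight_exponent = 1,
                         n_perm = 1000, seed) {
  seed <- check_seed(seed)
  stopifnot(!is.null(names(scores)), all(is.finite(scores)))
  ord <- order(-scores, names(scores))
  s <- scores[ord]
  ids <- names(scores)[ord]
  hit <- ids %in% target
  n_hit <- sum(hit)
  if (n_hit == 0) {
    return(list(es = NA_real_, nes = NA_real_, p_perm = NA_real_,
                n_hits = 0L, perm_es = numeric(0)))
  }
  if (n_hit == length(ids)) stop("target covers the whole universe",
                                 call. = FALSE)
  es <- running_es(s, hit, weight_exponent)
  withr::with_seed(seed, {
    perm <- vapply(seq_len(n_perm), function(i) {
      ph <- logical(length(ids))
      ph[sample.int(length(ids), n_hit)] <- TRUE
      running_es(s, ph, weight_exponent)
    }, 0)
  })
  same_sign <- perm[sign(perm) == sign(es)]
  nes <- if (length(same_sign) == 0) NA_real_ else es / mean(abs(same_sign))
  p_perm <- if (es >= 0) {
    (1 + sum(perm >= es)) / (1 + n_perm)
  } else {
    (1 + sum(perm <= es)) / (1 + n_perm)
  }
  list(es = es, nes = nes, p_perm = p_perm, n_hits = n_hit, perm_es = perm)
}

#' Enrichment of a query set against a collection of catalog sets
#'
#' Runs [fisher_overlap()] and [preranked_es()] for every set and adds a
#' permutation FDR q over the collection (fraction of pooled permuted NES at
#' least as extreme, divided by the fraction of observed NES at least as
#' extreme, clipped to [0, 1]; computed within each NES sign as in
#' pre-ranked GSEA).
#'
#' @param scores named ranking scores over the universe.
#' @param sets named list of catalog sets (`name`, `trait` or `description`,
#'   `ids`).
#' @param query CpG ids used for the Fisher overlap test (e.g. the
#'   significant smCpGs); defaults to the top `length(target)`-independent
#'   choice of all CpGs with score above 0.
#' @param weight_exponent,n_perm,seed passed to [preranked_es()].
#' @return data.frame: `set`, `trait`, `overlap`, `odds_ratio`, `fisher_p`,
#'   `es`, `nes`, `q`.
#' @export
enrich_collection <- function(scores, sets, query = NULL,
                              weight_exponent = 1, n_perm = 1000, seed) {
  seed <- check_seed(seed)
  universe <- names(scores)
  if (is.null(query)) query <- universe[scores > 0]
  rows <- list()
  all_perm <- list()
  for (i in seq_along(sets)) {
    s <- sets[[i]]
    fo <- fisher_overlap(query, s$ids, universe)
    pe <- preranked_es(scores, s$ids, weight_exponent, n_perm,
                       seed = seed + i)
    rows[[i]] <- data.frame(
      set = s$name, trait = s$trait %||% s$description %||% "",
      overlap = fo$overlap, odds_ratio = fo$odds_ratio, fisher_p = fo$p,
      es = pe$es, nes = pe$nes, stringsAsFactors = FALSE)
    # normalize permuted ES the same way as the observed ones
    if (length(pe$perm_es) > 0) {
      pos <- pe$perm_es[pe$perm_es > 0]
      neg <- pe$perm_es[pe$perm_es < 0]
      all_perm[[i]] <- c(if (length(pos)) pos / mean(pos),
                         if (length(neg)) -neg / mean(-neg) * -1)
    }
  }
  out <- do.call(rbind, rows)
  null_nes <- unlist(all_perm)
  out$q <- vapply(out$nes, function(nes) {
    if (is.na(nes)) return(NA_real_)
    if (nes >= 0) {
      num <- mean(null_nes >= nes)
      den <- mean(out$nes >= nes, na.rm = TRUE)
    } else {
      num <- mean(null_nes <= nes)
      den <- mean(out$nes <= nes, na.rm = TRUE)
    }
    min(1, num / max(den, .Machine$double.eps))
  }, 0)
  rownames(out) <- NULL
  out
}
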