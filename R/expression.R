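# Differential expression: qPCR relative expression (2^-ddCt), Dunnett
# many-to-one testing against the control condition, FPKM from fragment
# counts, and the fold-change/threshold call rules.

#' Relative expression by the 2^-ddCt method
#'
#' Per replicate, `dCt = Ct_target - Ct_reference` within the same condition
#' and replicate; `ddCt = dCt - mean(control dCt)`; `rq = 2^-ddCt`.  The
#' per-condition rq is the mean of replicate-level rq values
#' (`method = "mean"`, default) or `2^-mean(ddCt)` (`method = "geometric"`,
#' under which the control condition's rq is exactly 1).  Replicates whose
#' reference Ct is missing are dropped with a notice; a gene/condition with
#' no usable replicates is omitted.
#'
#' @param ct data.frame with columns gene_id, condition, replicate, ct.
#' @param reference_gene id of the internal-control gene (e.g. actin).
#' @param control_condition label of the control condition.
#' @param method replicate aggregation, "mean" or "geometric".
#' @return data.frame gene_id, condition, rq, n_reps; attribute `delta_ct`
#'   holds replicate-level dCt values for downstream testing.
#' @export
ddct <- function(ct, reference_gene, control_condition,
                 method = c("mean", "geometric")) {
  method <- match.arg(method)
  stopifnot(all(c("gene_id", "condition", "replicate", "ct") %in% names(ct)))
  if (!reference_gene %in% ct$gene_id) {
    stop("reference gene '", reference_gene, "' not in Ct table")
  }
  if (!control_condition %in% ct$condition) {
    stop("control condition '", control_condition, "' not in Ct table")
  }
  ref <- ct[ct$gene_id == reference_gene, , drop = FALSE]
  ref_key <- paste(ref$condition, ref$replicate, sep = "\r")
  targets <- ct[ct$gene_id != reference_gene, , drop = FALSE]
  idx <- match(paste(targets$condition, targets$replicate, sep = "\r"), ref_key)
  dropped <- is.na(idx) | is.na(ref$ct[idx]) | is.na(targets$ct)
  if (any(dropped)) {
    wrky_log("info", sum(dropped),
             " replicate(s) dropped (missing reference or target Ct)")
  }
  targets <- targets[!dropped, , drop = FALSE]
  targets$dct <- targets$ct - ref$ct[idx[!dropped]]
  rows <- list()
  dct_rows <- list()
  for (g in unique(targets$gene_id)) {
    tg <- targets[targets$gene_id == g, , drop = FALSE]
    ctrl_dct <- tg$dct[tg$condition == control_condition]
    if (length(ctrl_dct) == 0) {
      wrky_log("info", "gene '", g, "': no control replicates; omitted")
      next
    }
    tg$ddct <- tg$dct - mean(ctrl_dct)
    dct_rows[[g]] <- tg[, c("gene_id", "condition", "replicate", "dct", "ddct")]
    for (cond in unique(tg$condition)) {
      dd <- tg$ddct[tg$condition == cond]
      rq <- if (method == "mean") mean(2^(-dd)) else 2^(-mean(dd))
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = g, condition = cond, rq = rq, n_reps = length(dd),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "delta_ct") <- do.call(rbind, c(dct_rows,
                                            list(make.row.names = FALSE)))
  out
}

#' Dunnett many-to-one comparisons by seeded Monte Carlo
#'
#' Compares each treatment group against the control with pooled
#' within-group variance.  Two-sided p-values come from the multivariate-t
#' null with the standard many-to-one correlation
#' `rho_ij = lambda_i lambda_j`, `lambda_i = sqrt(n_i / (n_i + n0))`,
#' estimated by seeded Monte Carlo on `max |T|` (one sample serves all
#' contrasts); with the default 200,000 draws the p-values are accurate to
#' about +/-0.003.  Zero pooled variance is degenerate: p = 1 for equal
#' means, p = 0 (with a notice) otherwise.
#'
#' @param control numeric vector of control replicates (>= 2).
#' @param treatments named list of numeric vectors (>= 2 each).
#' @param n_draws Monte-Carlo draws.
#' @param seed integer RNG seed.
#' @return data.frame: group, estimate (mean difference), t, p.
#' @export
dunnett_test <- function(control, treatments, n_draws = 200000L, seed = 1L) {
  if (!is.list(treatments)) treatments <- list(trt = treatments)
  if (is.null(names(treatments))) {
    names(treatments) <- paste0("trt", seq_along(treatments))
  }
  sizes <- vapply(treatments, length, 1L)
  if (length(control) < 2 || any(sizes < 2)) {
    stop("each group needs at least 2 replicates")
  }
  groups <- c(list(control), treatments)
  N <- sum(lengths(groups))
  k <- length(groups)
  df <- N - k
  ss <- sum(vapply(groups, function(x) sum((x - mean(x))^2), numeric(1)))
  s2 <- ss / df
  n0 <- length(control)
  est <- vapply(treatments, mean, numeric(1)) - mean(control)
  if (s2 <= 0) {
    p <- ifelse(abs(est) < 1e-12, 1, 0)
    if (any(p == 0)) wrky_log("warn", "zero pooled variance with unequal means")
    return(data.frame(group = names(treatments), estimate = est,
                      t = ifelse(p == 1, 0, Inf) * sign(est), p = p,
                      row.names = NULL, stringsAsFactors = FALSE))
  }
  se <- sqrt(s2 * (1 / sizes + 1 / n0))
  tobs <- est / se
  lambda <- sqrt(sizes / (sizes + n0))
  set.seed(seed)
  z0 <- rnorm(n_draws)
  maxT <- rep(0, n_draws)
  s <- sqrt(rchisq(n_draws, df) / df)
  for (i in seq_along(treatments)) {
    Ti <- (sqrt(1 - lambda[i]^2) * rnorm(n_draws) + lambda[i] * z0) / s
    maxT <- pmax(maxT, abs(Ti))
  }
  p <- vapply(abs(tobs), function(cut) mean(maxT >= cut), numeric(1))
  data.frame(group = names(treatments), estimate = est, t = tobs, p = p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' One-way ANOVA omnibus F-test p-value
#'
#' Optional gate ahead of the Dunnett comparisons.
#'
#' @param groups list of numeric vectors (control first).
#' @return p-value of the omnibus F test.
#' @export
anova_omnibus <- function(groups) {
  x <- unlist(groups)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  summary(stats::aov(x ~ g))[[1]][["Pr(>F)"]][1]
}

#' Call qPCR differential expression
#'
#' Up: `rq > up` and `p < alpha`; down: `rq <= down` and `p < alpha`;
#' otherwise unchanged (thresholds follow the survey protocol: 1.5, 0.66,
#' 0.05, with the strict/non-strict mix as stated).
#'
#' @param rq_table data.frame with gene_id, condition, rq, p.
#' @param up,down fold-change thresholds.
#' @param alpha significance level.
#' @return the input with a `call` column (up/down/unchanged).
#' @export
call_de_qpcr <- function(rq_table, up = 1.5, down = 0.66, alpha = 0.05) {
  stopifnot(all(c("rq", "p") %in% names(rq_table)))
  rq_table$call <- ifelse(rq_table$rq > up & rq_table$p < alpha, "up",
                   ifelse(rq_table$rq <= down & rq_table$p < alpha, "down",
                          "unchanged"))
  rq_table
}

#' qPCR pipeline: ddCt, Dunnett per gene, threshold calls
#'
#' @inheritParams ddct
#' @param config a [wrky_config()] (alpha, thresholds, MC draws, seed).
#' @param omnibus_gate require omnibus ANOVA p < alpha before any call
#'   (default FALSE; the protocol leaves this unstated).
#' @return data.frame: gene_id, condition, rq, p, call.
#' @export
qpcr_calls <- function(ct, reference_gene, control_condition,
                       config = wrky_config(), omnibus_gate = FALSE) {
  rq <- ddct(ct, reference_gene, control_condition)
  dct <- attr(rq, "delta_ct")
  rq$p <- NA_real_
  for (g in unique(rq$gene_id)) {
    dg <- dct[dct$gene_id == g, , drop = FALSE]
    ctrl <- dg$dct[dg$condition == control_condition]
    conds <- setdiff(unique(dg$condition), control_condition)
    if (length(conds) == 0) next
    trts <- lapply(setNames(conds, conds),
                   function(cc) dg$dct[dg$condition == cc])
    dt <- dunnett_test(ctrl, trts, n_draws = config$n_draws,
                       seed = config$seed)
    gate_ok <- !omnibus_gate ||
      anova_omnibus(c(list(ctrl), trts)) < config$alpha
    for (cc in conds) {
      pv <- dt$p[dt$group == cc]
      rq$p[rq$gene_id == g & rq$condition == cc] <-
        if (gate_ok) pv else max(pv, 1)
    }
    rq$p[rq$gene_id == g & rq$condition == control_condition] <- 1
  }
  out <- call_de_qpcr(rq, config$up, config$down, config$alpha)
  out$call[is.na(out$p)] <- "unchanged"
  out
}

#' FPKM from fragment counts
#'
#' `fpkm = count * 1e9 / (gene_length * sample_total_count)`.
#'
#' @param counts data.frame with columns gene_id, sample, count, length.
#' @return the input with an `fpkm` column.
#' @export
fpkm <- function(counts) {
  stopifnot(all(c("gene_id", "sample", "count", "length") %in% names(counts)))
  if (any(counts$length <= 0)) stop("gene lengths must be positive")
  totals <- tapply(counts$count, counts$sample, sum)
  if (any(totals <= 0)) {
    stop("sample '", names(totals)[totals <= 0][1], "' has zero total count")
  }
  counts$fpkm <- counts$count * 1e9 /
    (counts$length * as.numeric(totals[counts$sample]))
  counts
}

#' Call RNA-seq differential expression from FPKM replicates
#'
#' A gene is valid when its mean FPKM exceeds `validity` in either arm.
#' Fold change is `mean(treated) / mean(control)` (+Inf sentinel when the
#' control mean is 0 and the treated mean positive).  The deviation
#' probability is the seeded-bootstrap (replicates resampled with
#' replacement in both arms) fraction of resamples whose fold change stays
#' beyond the relevant threshold.  Up: `fc >= up` and `prob >= prob_min`;
#' down: `fc <= down` and `prob >= prob_min`.
#'
#' @param control_fpkm,treated_fpkm matrices (genes x replicates) of FPKM
#'   values with matching rownames.
#' @param validity FPKM validity threshold (default 10).
#' @param up,down fold-change thresholds.
#' @param prob_min deviation-probability threshold (default 0.8).
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed integer RNG seed.
#' @return data.frame: gene_id, mean_control, mean_treated, valid,
#'   fold_change, deviation_probability, call (NA for invalid genes).
#' @export
call_de_fpkm <- function(control_fpkm, treated_fpkm, validity = 10,
                         up = 1.5, down = 0.66, prob_min = 0.8,
                         n_boot = 1000L, seed = 1L) {
  control_fpkm <- as.matrix(control_fpkm)
  treated_fpkm <- as.matrix(treated_fpkm)
  stopifnot(nrow(control_fpkm) == nrow(treated_fpkm))
  if (ncol(control_fpkm) < 2 || ncol(treated_fpkm) < 2) {
    stop("each arm needs at least 2 replicates")
  }
  genes <- rownames(control_fpkm)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(control_fpkm)))
  nc <- ncol(control_fpkm); nt <- ncol(treated_fpkm)
  set.seed(seed)
  boot_c <- matrix(sample.int(nc, n_boot * nc, replace = TRUE), n_boot, nc)
  boot_t <- matrix(sample.int(nt, n_boot * nt, replace = TRUE), n_boot, nt)
  fc_of <- function(mt, mc) {
    if (mc == 0) { if (mt > 0) Inf else 1 } else mt / mc
  }
  rows <- lapply(seq_along(genes), function(i) {
    mc <- mean(control_fpkm[i, ]); mt <- mean(treated_fpkm[i, ])
    valid <- mc > validity || mt > validity
    fc <- fc_of(mt, mc)
    prob <- NA_real_
    call <- NA_character_
    if (valid) {
      bfc <- vapply(seq_len(n_boot), function(b) {
        fc_of(mean(treated_fpkm[i, boot_t[b, ]]),
              mean(control_fpkm[i, boot_c[b, ]]))
      }, numeric(1))
      if (fc >= up) {
        prob <- mean(bfc >= up)
        call <- if (prob >= prob_min) "up" else "unchanged"
      } else if (fc <= down) {
        prob <- mean(bfc <= down)
        call <- if (prob >= prob_min) "down" else "unchanged"
      } else {
        prob <- 0
        call <- "unchanged"
      }
    }
    data.frame(gene_id = genes[i], mean_control = mc, mean_treated = mt,
               valid = valid, fold_change = fc, deviation_probability = prob,
               call = call, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Heat-map scaling of relative expression
#'
#' `log(rq, base = 1.5)` -- an output formatting option for clustered
#' displays, not a separate statistic.
#'
#' @param rq numeric vector of relative expression values.
#' @return numeric vector.
#' @export
log15 <- function(rq) log(rq, base = 1.5)
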