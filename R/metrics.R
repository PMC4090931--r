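# Static, dynamic and cellular histomorphometry measurements.
#
# Surface-fraction fields are class pixel counts over total surface pixels.
# Derived fields follow the standard conventions: LS/BS = sLS/BS + dLS/BS,
# MS/BS = dLS/BS + sLS/BS / 2 (Parfitt), MAR = mean Ir.L.Th over the
# label interval, BFR = MAR x MS/BS (fraction form). Ratios with an empty
# denominator are absent (NULL), never zero.

#' Static measurements within the ROI
#'
#' BV/TV is the bone area fraction of the ROI. Tb.Th is measured directly as
#' twice the mean distance from medial-axis pixels of the bone to the bone
#' boundary. Tb.N and Tb.Sp are derived under the parallel-plate model:
#' Tb.N = (BV/TV) / Tb.Th (per mm), Tb.Sp = 1/Tb.N - Tb.Th.
#'
#' @param bone a [binary_mask()] (raw segmentation, not the smoothed one).
#' @param roi an ROI mask.
#' @return list(bv_tv, tb_th, tb_n, tb_sp); tb_* are NULL when the ROI holds
#'   no bone.
#' @export
static_metrics <- function(bone, roi) {
  ps <- pixel_size(bone)
  b <- as_plain(bone) > 0; r <- as_plain(roi) > 0
  if (!any(r)) stop("empty ROI")
  n_roi <- sum(r)
  n_bone <- sum(b & r)
  bv_tv <- 100 * n_bone / n_roi
  if (n_bone == 0)
    return(list(bv_tv = 0, tb_th = NULL, tb_n = NULL, tb_sp = NULL))
  D <- EBImage::distmap(b)
  # medial axis: ridge (8-neighbourhood local maxima) of the distance map
  nr <- nrow(D); nc <- ncol(D)
  pad <- matrix(-Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- D
  nbmax <- pmax(pad[1:nr, 1:nc], pad[1:nr, 2:(nc + 1)], pad[1:nr, 3:(nc + 2)],
                pad[2:(nr + 1), 1:nc], pad[2:(nr + 1), 3:(nc + 2)],
                pad[3:(nr + 2), 1:nc], pad[3:(nr + 2), 2:(nc + 1)],
                pad[3:(nr + 2), 3:(nc + 2)])
  medial <- b & r & (D >= nbmax) & D > 0
  if (!any(medial))
    return(list(bv_tv = bv_tv, tb_th = NULL, tb_n = NULL, tb_sp = NULL))
  tb_th <- 2 * mean(D[medial]) * ps
  tb_n_per_mm <- (bv_tv / 100) / tb_th * 1000
  tb_sp <- 1000 / tb_n_per_mm - tb_th
  list(bv_tv = bv_tv, tb_th = tb_th, tb_n = tb_n_per_mm, tb_sp = tb_sp)
}

#' Derived dynamic measurements from surface fractions
#'
#' The calculated-column arithmetic of the dynamic measurement set, usable
#' directly on measured surface fractions (percent): LS/BS, MS/BS, L1/BS,
#' L2/BS, label-surface proportions, MAR and BFR.
#'
#' @param sls_bs,dls_bs single- and double-labeled surface per bone surface,
#'   percent.
#' @param l1_only_bs,l2_only_bs exclusive single-label fractions, percent
#'   (optional).
#' @param ir_l_th_um mean inter-label thickness, micrometers (optional).
#' @param label_interval_days days between the two label injections.
#' @return named list of derived fields; entries with empty denominators are
#'   NULL.
#' @export
dynamic_from_fractions <- function(sls_bs, dls_bs, l1_only_bs = NULL,
                                   l2_only_bs = NULL, ir_l_th_um = NULL,
                                   label_interval_days = 5) {
  if (label_interval_days <= 0) stop("label_interval_days must be > 0")
  ls_bs <- sls_bs + dls_bs
  ms_bs <- dls_bs + sls_bs / 2
  out <- list(
    sls_bs = sls_bs, dls_bs = dls_bs, ls_bs = ls_bs, ms_bs = ms_bs,
    l1_only_bs = l1_only_bs, l2_only_bs = l2_only_bs,
    l1_bs = if (!is.null(l1_only_bs)) l1_only_bs + dls_bs,
    l2_bs = if (!is.null(l2_only_bs)) l2_only_bs + dls_bs,
    sls_ls = if (ls_bs > 0) 100 * sls_bs / ls_bs,
    dls_ls = if (ls_bs > 0) 100 * dls_bs / ls_bs,
    dls_sls = if (sls_bs > 0) 100 * dls_bs / sls_bs,
    ir_l_th = ir_l_th_um,
    mar = if (!is.null(ir_l_th_um)) ir_l_th_um / label_interval_days,
    label_interval_days = label_interval_days)
  out$bfr <- if (!is.null(out$mar)) out$mar * ms_bs / 100
  out
}

#' Dynamic measurements from a surface classification
#'
#' @param cls a [classify_surface()] result (optionally subset to the ROI
#'   surface).
#' @param ir an [interlabel_thickness()] result (or NULL when absent).
#' @param label_interval_days days between the two label injections
#'   (default 5: injections 7 and 2 days before sacrifice).
#' @return named list of dynamic fields (percent, um, um/day).
#' @export
dynamic_metrics <- function(cls, ir = NULL, label_interval_days = 5) {
  n <- nrow(cls)
  if (n == 0) stop("zero surface: classification is empty")
  f <- function(flag) 100 * sum(flag) / n
  ir_um <- if (!is.null(ir) && !isTRUE(ir$absent)) ir$mean_um else NULL
  dynamic_from_fractions(
    sls_bs = f(cls$sL1 | cls$sL2), dls_bs = f(cls$dL),
    l1_only_bs = f(cls$sL1), l2_only_bs = f(cls$sL2),
    ir_l_th_um = ir_um, label_interval_days = label_interval_days)
}

#' Cellular measurements
#'
#' Surface fractions (AP/BS, AP_L2/BS, AP_only/BS, TRAP/BS, TRAP_L2/BS,
#' TRAP_only/BS) come from the surface classification. TRAP/TV is the TRAP
#' area fraction of the ROI; TRAP_on/TRAP is the proportion of the TRAP
#' area within `proximity_um` of the bone surface.
#'
#' @param cls a [classify_surface()] result (subset to the ROI surface).
#' @param trap_mask TRAP channel [binary_mask()].
#' @param bone bone [binary_mask()] (for surface proximity).
#' @param roi ROI mask.
#' @param proximity_um proximity rule, default 25.6.
#' @return named list of cellular fields; trap_on_trap is NULL when the ROI
#'   holds no TRAP signal.
#' @export
cellular_metrics <- function(cls, trap_mask, bone, roi, proximity_um = 25.6) {
  ps <- pixel_size(trap_mask)
  r <- as_plain(roi) > 0
  if (!any(r)) stop("empty ROI")
  n <- nrow(cls)
  f <- function(flag) if (n > 0) 100 * sum(flag) / n else NULL
  tm <- as_plain(trap_mask) > 0
  b <- as_plain(bone) > 0
  trap_in <- tm & r
  trap_tv <- 100 * sum(trap_in) / sum(r)
  trap_on_trap <- NULL
  if (any(trap_in)) {
    dist_to_bone <- EBImage::distmap(!b) * ps
    trap_on_trap <- 100 * sum(trap_in & dist_to_bone <= proximity_um) / sum(trap_in)
  }
  list(ap_bs = f(cls$AP), ap_l2_bs = f(cls$AP_L2), ap_only_bs = f(cls$AP_only),
       trap_bs = f(cls$TRAP), trap_l2_bs = f(cls$TRAP_L2),
       trap_only_bs = f(cls$TRAP_only),
       trap_tv = trap_tv, trap_on_trap = trap_on_trap)
}

#' Assemble a histomorphometry report
#'
#' @param static,dynamic,cellular results of [static_metrics()],
#'   [dynamic_metrics()], [cellular_metrics()] (any may be omitted).
#' @param values alternatively, a flat named list of measurement values.
#' @param provenance list of run metadata (config snapshot, pixel size,
#'   site, label interval, ...).
#' @return a `histomorphometry_report`.
#' @export
build_report <- function(static = NULL, dynamic = NULL, cellular = NULL,
                         values = NULL, provenance = list()) {
  schema <- report_schema()
  vals <- setNames(vector("list", length(schema)), names(schema))
  pick <- function(lst) {
    for (nm in intersect(names(lst), names(schema)))
      vals[[nm]] <<- lst[[nm]]
  }
  if (!is.null(static)) pick(static)
  if (!is.null(dynamic)) pick(dynamic)
  if (!is.null(cellular)) pick(cellular)
  if (!is.null(values)) pick(values)
  structure(list(values = vals, provenance = provenance),
            class = "histomorphometry_report")
}

report_values <- function(report) report$values

#' @export
print.histomorphometry_report <- function(x, ...) {
  cat("<histomorphometry_report>\n")
  schema <- report_schema()
  for (nm in names(schema)) {
    v <- x$values[[nm]]
    cat(sprintf("  %-14s %s %s\n", nm,
                if (is.null(v)) "absent" else format(round(v, 3)),
                if (is.null(v)) "" else schema[[nm]]))
  }
  invisible(x)
}

#' Paired comparison of two report groups
#'
#' Paired two-sided t test per measurement; pairs with an absent value on
#' either side are deleted pairwise. Fewer than 2 complete pairs, or a
#' zero-variance nonzero difference, yields an absent p (flagged
#' degenerate); identical groups give t = 0, p = 1.
#'
#' @param a,b equal-length lists of `histomorphometry_report`, paired by
#'   index.
#' @return data.frame: measurement, mean_a, mean_b, sd_a, sd_b, t, p, n,
#'   degenerate.
#' @export
compare_groups <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2)
    stop("need two equal-length groups with >= 2 paired reports")
  schema <- report_schema()
  out <- NULL
  for (nm in names(schema)) {
    va <- vapply(a, function(r) r$values[[nm]] %||% NA_real_, numeric(1))
    vb <- vapply(b, function(r) r$values[[nm]] %||% NA_real_, numeric(1))
    ok <- !is.na(va) & !is.na(vb)
    n <- sum(ok)
    tstat <- NA_real_; pval <- NA_real_; degen <- FALSE
    if (n >= 2) {
      d <- va[ok] - vb[ok]
      if (sd(d) == 0) {
        if (all(d == 0)) { tstat <- 0; pval <- 1 } else degen <- TRUE
      } else {
        tt <- t.test(va[ok], vb[ok], paired = TRUE)
        tstat <- unname(tt$statistic); pval <- tt$p.value
      }
    }
    out <- rbind(out, data.frame(
      measurement = nm,
      mean_a = if (n) mean(va[ok]) else NA_real_,
      mean_b = if (n) mean(vb[ok]) else NA_real_,
      sd_a = if (n > 1) sd(va[ok]) else NA_real_,
      sd_b = if (n > 1) sd(vb[ok]) else NA_real_,
      t = tstat, p = pval, n = n, degenerate = degen))
  }
  out
}
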