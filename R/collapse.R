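# Comparison orchestration: group definitions, block-pairing enumeration,
# nearest-neighbour collapse of pair measures onto residues, four-block
# averaging, and the full pipeline from trajectories to per-residue
# measure and significance profiles.

.TABLE_GROUPS <- list(
  "1R-self-1"  = list(mode = "1R", alignment = "self", averaging = "local",
                      pairs = c("A-A", "B-B", "C-C", "X-X", "Y-Y", "Z-Z")),
  "1R-self-2"  = list(mode = "1R", alignment = "self", averaging = "global",
                      pairs = c("A-A", "B-B", "C-C", "X-X", "Y-Y", "Z-Z")),
  "1R-wt-wt-1" = list(mode = "1R", alignment = "self", averaging = "local",
                      pairs = c("A-B", "A-C", "B-C")),
  "1R-wt-wt-2" = list(mode = "1R", alignment = "mean", averaging = "local",
                      pairs = c("A-B", "A-C", "B-C")),
  "1R-mt-wt-1" = list(mode = "1R", alignment = "self", averaging = "local",
                      pairs = c("X-A", "X-B", "X-C", "Y-A", "Y-B", "Y-C",
                                "Z-A", "Z-B", "Z-C")),
  "1R-mt-wt-2" = list(mode = "1R", alignment = "mean", averaging = "local",
                      pairs = c("X-A", "X-B", "X-C", "Y-A", "Y-B", "Y-C",
                                "Z-A", "Z-B", "Z-C")),
  "2R-wt-wt-1" = list(mode = "2R", alignment = "none", averaging = "local",
                      pairs = c("A-B", "A-C", "B-C")),
  "2R-mt-wt-1" = list(mode = "2R", alignment = "none", averaging = "local",
                      pairs = c("X-A", "X-B", "X-C", "Y-A", "Y-B", "Y-C",
                                "Z-A", "Z-B", "Z-C")),
  "2R-wt-wt-2" = list(mode = "2R", alignment = "none", averaging = "shifting",
                      pairs = c("A-B", "A-C", "B-C")),
  "2R-mt-wt-2" = list(mode = "2R", alignment = "none", averaging = "shifting",
                      pairs = c("X-A", "X-B", "X-C", "Y-A", "Y-B", "Y-C",
                                "Z-A", "Z-B", "Z-C"))
)

#' Define a comparison group
#'
#' The ten standard groups (1R-self-1, 1R-self-2, 1R-wt-wt-1/2,
#' 1R-mt-wt-1/2, 2R-wt-wt-1/2, 2R-mt-wt-1/2) are built in, with wildtype
#' trajectories labelled A, B, C and mutants X, Y, Z. Custom groups give
#' mode/alignment/averaging/pairs explicitly.
#'
#' @param name group name; one of the built-in names, or any label when
#'   the remaining arguments are supplied.
#' @param mode "1R" (on-residue displacement magnitudes) or "2R"
#'   (residue-pair distances).
#' @param alignment "self", "mean" or "none" (2R).
#' @param averaging "local", "global" or "shifting" (2R only).
#' @param pairs character vector like c("A-B", "A-C") or list of length-2
#'   label vectors; "A-A" denotes a self (half-vs-half) comparison.
#' @return a [ComparisonGroup-class].
#' @export
comparisonGroup <- function(name, mode = NULL, alignment = NULL,
                            averaging = NULL, pairs = NULL) {
  if (is.null(mode) && is.null(pairs)) {
    def <- .TABLE_GROUPS[[name]]
    if (is.null(def)) stop("unknown comparison group: ", name)
    mode <- def$mode; alignment <- def$alignment
    averaging <- def$averaging; pairs <- def$pairs
  }
  if (is.character(pairs)) pairs <- strsplit(pairs, "-", fixed = TRUE)
  new("ComparisonGroup", name = name, mode = mode, alignment = alignment,
      averaging = averaging, pairs = pairs)
}

setMethod("show", "ComparisonGroup", function(object) {
  cat("ComparisonGroup", object@name, ":", object@mode, "/",
      object@alignment, "alignment /", object@averaging, "averaging\n")
  cat("  pairs:", paste(vapply(object@pairs, paste, "", collapse = "-"),
                        collapse = ", "), "\n")
})

#' Enumerate the sample-pair tasks of a comparison group
#'
#' A self comparison of trajectory A tests its two half blocks (A1, A2):
#' one task. A cross comparison of A and B tests the four block pairings
#' {A1&B1, A2&B1, A1&B2, A2&B2}: four tasks.
#'
#' @param group a [ComparisonGroup-class].
#' @return data.frame with columns pair, labelA, blockA, labelB, blockB.
#' @export
enumerateComparisons <- function(group) {
  rows <- lapply(group@pairs, function(p) {
    pairName <- paste(p, collapse = "-")
    if (p[1L] == p[2L]) {
      data.frame(pair = pairName, labelA = p[1L], blockA = 1L,
                 labelB = p[2L], blockB = 2L)
    } else {
      data.frame(pair = pairName,
                 labelA = p[1L], blockA = c(1L, 2L, 1L, 2L),
                 labelB = p[2L], blockB = c(1L, 1L, 2L, 2L))
    }
  })
  do.call(rbind, rows)
}

#' Collapse residue-pair measures onto residues
#'
#' M̄_k is the arithmetic mean of M_kj over all nearest neighbours j of
#' residue k in the supplied neighbour set (for cross-trajectory
#' comparisons, the intersection of the two trajectories' neighbour sets).
#' Residues of the neighbour set with no pairs after intersection are
#' omitted with a warning.
#'
#' @param pairMeasures data.frame with columns k, j, value (one row per
#'   residue pair).
#' @param neighbors data.frame with columns k, j defining which pairs
#'   participate (default: all rows of `pairMeasures`).
#' @return named numeric vector M̄_k indexed by residue id.
#' @export
neighborCollapse <- function(pairMeasures, neighbors = NULL) {
  if (is.null(neighbors)) neighbors <- pairMeasures[, c("k", "j")]
  key <- function(d) paste(d$k, d$j, sep = "|")
  keep <- pairMeasures[key(pairMeasures) %in% key(neighbors), , drop = FALSE]
  resids <- sort(unique(c(neighbors$k, neighbors$j)))
  long <- rbind(data.frame(res = keep$k, value = keep$value),
                data.frame(res = keep$j, value = keep$value))
  m <- tapply(long$value, long$res, mean)
  out <- as.vector(m[as.character(resids)])
  names(out) <- resids
  if (anyNA(out)) {
    warning("residues with no neighbours omitted: ",
            paste(resids[is.na(out)], collapse = ", "))
    out <- out[!is.na(out)]
  }
  out
}

#' Average per-residue profiles over block pairings
#'
#' Elementwise arithmetic mean of up to four per-residue profiles
#' ⟨M̄_k⟩ = mean over the block pairings {A1&B1, A2&B1, A1&B2, A2&B2};
#' profiles are matched by residue name and intersected if their residue
#' sets differ. A single profile (self comparison) passes through.
#'
#' @param profiles list of named numeric vectors (residue id → value).
#' @return named numeric vector on the common residue set.
#' @export
blockAverage <- function(profiles) {
  if (!length(profiles)) stop("no profiles to average")
  common <- Reduce(intersect, lapply(profiles, names))
  vals <- vapply(profiles, function(p) p[common],
                 numeric(length(common)))
  if (length(common) == 1L) vals <- matrix(vals, nrow = 1L)
  out <- rowMeans(vals)
  names(out) <- common
  out
}

# Deterministic per-fit sub-seed below 2^31.
.subSeed <- function(seed, i, j, k) {
  (((seed %% 65536) * 1009 + i * 7919 + j * 104729 + k * 31) %%
     2147483647L) + 1L
}

.MEASURE_COLS <- c("delta_rmsf", "js", "delta_p", "kl_min", "kl_ave",
                   "kl_max", "ks1", "ks0", "log10pv_ks1", "log10pv_ks0")

# Aggregate task-level per-unit measure rows into per-pair profiles:
# plain measures averaged arithmetically, p-values on the log10 scale
# (geometric mean of pv).
.aggregateProfiles <- function(panels) {
  agg <- stats::aggregate(panels[, .MEASURE_COLS],
                          by = list(pair = panels$pair, id = panels$id),
                          FUN = mean)
  agg$pv_ks1 <- 10^agg$log10pv_ks1
  agg$pv_ks0 <- 10^agg$log10pv_ks0
  agg[order(agg$pair, agg$id), , drop = FALSE]
}

#' Run a comparison group end to end
#'
#' Full pipeline: (alignment →) fluctuation-variable extraction → density
#' estimation per sample → eight-measure panels per block pairing →
#' (nearest-neighbour collapse for 2R →) four-block averaging →
#' per-residue measure and log10 p-value significance profiles.
#' Deterministic given the master seed.
#'
#' @param group a [ComparisonGroup-class].
#' @param trajectories named list of [Trajectory-class] objects covering
#'   the labels in the group's pairs; all on the same residue set.
#' @param cutoff neighbour cutoff in Å for 2R (default 12).
#' @param seed master seed (default 1).
#' @param control density-estimation settings, see [maxentControl()].
#' @param verbose print progress to stderr.
#' @return a [ComparisonResult-class]; `profiles` hold the block-averaged
#'   per-residue measures with pv/log10pv columns, `panels` the raw rows
#'   (per residue or residue pair, per block pairing).
#' @export
runGroup <- function(group, trajectories, cutoff = 12, seed = 1L,
                     control = maxentControl(), verbose = FALSE) {
  labels <- unique(unlist(group@pairs))
  missing <- setdiff(labels, names(trajectories))
  if (length(missing))
    stop("trajectories missing for labels: ", paste(missing, collapse = ", "))
  trajectories <- trajectories[labels]
  nres <- vapply(trajectories, nResidues, integer(1))
  if (length(unique(nres)) != 1L)
    stop("residue-count mismatch between trajectories")
  ids0 <- residueIds(trajectories[[1L]])
  for (tr in trajectories)
    if (!identical(residueIds(tr), ids0))
      stop("residue ids differ between trajectories")

  tasks <- enumerateComparisons(group)
  panels <- if (group@mode == "1R")
    .run1R(group, trajectories, tasks, seed, control, verbose)
  else
    .run2R(group, trajectories, tasks, cutoff, seed, control, verbose)

  profiles <- .aggregateProfiles(panels$profileRows)
  new("ComparisonResult", group = group, panels = panels$panelRows,
      profiles = profiles,
      cutoff = if (group@mode == "2R") cutoff else NA_real_,
      seed = as.integer(seed))
}

# ---- 1R pipeline -------------------------------------------------------------

.run1R <- function(group, trajectories, tasks, seed, control, verbose) {
  labels <- names(trajectories)
  reference <- switch(group@alignment,
    self = NULL,
    mean = makeMeanReference(lapply(trajectories, frame0)),
    stop("1R comparisons need 'self' or 'mean' alignment"))
  mags <- vector("list", length(labels)); names(mags) <- labels
  for (L in labels) {
    aligned <- alignTrajectory(trajectories[[L]], reference)
    blocks <- splitHalves(aligned)
    mags[[L]] <- displacementMagnitudes(blocks[[1L]], blocks[[2L]],
      averaging = if (group@averaging == "global") "global" else "local")
  }
  ids <- residueIds(trajectories[[1L]])

  fits <- new.env(parent = emptyenv())
  getFit <- function(L, blk, r) {
    key <- paste(L, blk, r, sep = ":")
    est <- fits[[key]]
    if (is.null(est)) {
      est <- estimateDensity(mags[[L]][[blk]][, r], nonnegative = TRUE,
        seed = .subSeed(seed, match(L, labels), blk, r), control = control)
      fits[[key]] <- est
    }
    est
  }

  rows <- vector("list", nrow(tasks) * length(ids)); ri <- 1L
  for (tk in seq_len(nrow(tasks))) {
    t <- tasks[tk, ]
    if (verbose)
      message("1R task ", t$labelA, t$blockA, "-", t$labelB, t$blockB)
    for (r in seq_along(ids)) {
      a <- mags[[t$labelA]][[t$blockA]][, r]
      b <- mags[[t$labelB]][[t$blockB]][, r]
      panel <- measurePanel(a, getFit(t$labelA, t$blockA, r),
                            b, getFit(t$labelB, t$blockB, r))
      rows[[ri]] <- cbind(
        data.frame(group = group@name, pair = t$pair,
                   comparison = paste0(t$labelA, t$blockA, "-",
                                       t$labelB, t$blockB),
                   id = ids[r]),
        panel)
      ri <- ri + 1L
    }
  }
  panelRows <- do.call(rbind, rows)
  list(panelRows = panelRows, profileRows = panelRows)
}

# ---- 2R pipeline -------------------------------------------------------------

.run2R <- function(group, trajectories, tasks, cutoff, seed, control,
                   verbose) {
  labels <- names(trajectories)
  pd <- lapply(trajectories, pairDistances, cutoff = cutoff)
  halves <- lapply(pd, function(p) {
    nf <- nrow(p$distances)
    nf2 <- nf - nf %% 2L
    h <- nf2 / 2L
    list(p$distances[seq_len(h), , drop = FALSE],
         p$distances[h + seq_len(h), , drop = FALSE])
  })
  shifting <- group@averaging == "shifting"

  fits <- new.env(parent = emptyenv())
  getFit <- function(L, blk, key) {
    ck <- paste(L, blk, key, sep = ":")
    got <- fits[[ck]]
    if (is.null(got)) {
      x <- halves[[L]][[blk]][, key]
      est <- estimateDensity(x, nonnegative = TRUE,
        seed = .subSeed(seed, match(L, labels), blk,
                        match(key, colnames(pd[[L]]$distances))),
        control = control)
      got <- if (shifting) shiftDistribution(x, est)
             else list(sample = x, estimate = est)
      fits[[ck]] <- got
    }
    got
  }

  panelList <- list(); profileList <- list()
  for (tk in seq_len(nrow(tasks))) {
    t <- tasks[tk, ]
    keysA <- colnames(pd[[t$labelA]]$distances)
    keysB <- colnames(pd[[t$labelB]]$distances)
    keys <- intersect(keysA, keysB)   # intersection rule
    if (!length(keys)) {
      warning("no common neighbour pairs for comparison ", t$pair)
      next
    }
    if (verbose)
      message("2R task ", t$labelA, t$blockA, "-", t$labelB, t$blockB,
              " (", length(keys), " pairs)")
    rows <- vector("list", length(keys))
    for (i in seq_along(keys)) {
      fa <- getFit(t$labelA, t$blockA, keys[i])
      fb <- getFit(t$labelB, t$blockB, keys[i])
      panel <- measurePanel(fa$sample, fa$estimate, fb$sample, fb$estimate)
      rows[[i]] <- cbind(
        data.frame(group = group@name, pair = t$pair,
                   comparison = paste0(t$labelA, t$blockA, "-",
                                       t$labelB, t$blockB),
                   id = keys[i]),
        panel)
    }
    taskPanel <- do.call(rbind, rows)
    panelList[[length(panelList) + 1L]] <- taskPanel

    # collapse each measure onto residues for this task
    kj <- do.call(rbind, strsplit(keys, "|", fixed = TRUE))
    nb <- data.frame(k = as.integer(kj[, 1L]), j = as.integer(kj[, 2L]))
    collapsed <- lapply(.MEASURE_COLS, function(mc)
      neighborCollapse(cbind(nb, value = taskPanel[[mc]])))
    names(collapsed) <- .MEASURE_COLS
    resids <- names(collapsed[[1L]])
    prof <- data.frame(group = group@name, pair = t$pair,
                       comparison = taskPanel$comparison[1L],
                       id = as.integer(resids))
    for (mc in .MEASURE_COLS) prof[[mc]] <- unname(collapsed[[mc]])
    profileList[[length(profileList) + 1L]] <- prof
  }
  list(panelRows = do.call(rbind, panelList),
       profileRows = do.call(rbind, profileList))
}

# ---- result accessors --------------------------------------------------------

#' Per-residue significance profile of a comparison result
#'
#' @param result a [ComparisonResult-class].
#' @param pair optional pair name to select (default: all pairs).
#' @return data.frame with pair, id (residue), pv_ks1 and log10pv_ks1.
#' @export
significanceProfile <- function(result, pair = NULL) {
  p <- result@profiles
  if (!is.null(pair)) p <- p[p$pair %in% pair, , drop = FALSE]
  p[, c("pair", "id", "pv_ks1", "log10pv_ks1")]
}

setMethod("show", "ComparisonResult", function(object) {
  cat("ComparisonResult for group", object@group@name, "\n")
  cat("  ", nrow(object@panels), "panel rows,",
      nrow(object@profiles), "profile rows\n")
  if (nrow(object@profiles)) {
    cat("  median per-residue pv(KS1):",
        format(stats::median(object@profiles$pv_ks1), digits = 3), "\n")
  }
})

#' Plot a significance profile along the backbone
#'
#' @param result a [ComparisonResult-class].
#' @param pair optional pair selection.
#' @param ... further arguments to [graphics::plot()].
#' @return invisibly, the plotted data.frame.
#' @export
plotSignificance <- function(result, pair = NULL, ...) {
  p <- significanceProfile(result, pair)
  graphics::plot(p$id, p$log10pv_ks1, type = "h",
                 xlab = "residue", ylab = expression(log[10](pv)), ...)
  invisible(p)
}
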