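# Construction, I/O and validation of intervertebral-distance templates.

#' Build a distance template from labeled subjects
#'
#' Each subject contributes the distances between its adjacent hand-labeled
#' disks; per gap, the across-subject mean (the generic distance) and sample
#' standard deviation (n - 1 denominator) are recorded together with the
#' number of covering subjects. Subjects may cover different contiguous level
#' ranges; a gap covered by fewer than two subjects gets an undefined SD and
#' a warning.
#'
#' @param subjects list; each element a list with \code{firstLevel} (upper
#'   vertebral index or name of the subject's most rostral disk) and
#'   \code{positionsMm} (strictly increasing disk positions in mm).
#' @return a \linkS4class{DiskTemplate}.
#' @examples
#' buildTemplate(list(
#'   list(firstLevel = 2, positionsMm = c(0, 18, 38, 60)),
#'   list(firstLevel = 2, positionsMm = c(0, 18, 38, 60))))
#' @export
buildTemplate <- function(subjects) {
  if (!is.list(subjects) || !length(subjects)) stop("need at least one subject")
  rows <- list()
  for (i in seq_along(subjects)) {
    sj <- subjects[[i]]
    pos <- sj$positionsMm
    if (is.null(pos) || length(pos) < 2L)
      stop(sprintf("subject %d has fewer than 2 disk positions", i))
    if (any(diff(pos) <= 0))
      stop(sprintf("subject %d rejected: disk positions are not strictly increasing", i))
    first <- levelIndex(if (is.null(sj$firstLevel)) 2L else sj$firstLevel)
    upper <- first + seq_len(length(pos) - 1L) - 1L
    rows[[i]] <- data.frame(upper_level = upper, gap = diff(pos))
  }
  all <- do.call(rbind, rows)
  levs <- sort(unique(all$upper_level))
  if (length(levs) > 1L && any(diff(levs) != 1L))
    stop("subjects do not cover a contiguous level range")
  agg <- lapply(levs, function(l) {
    g <- all$gap[all$upper_level == l]
    data.frame(upper_level = l, lower_level = l + 1L, mean_mm = mean(g),
               sd_mm = if (length(g) >= 2L) stats::sd(g) else NA_real_,
               n = length(g))
  })
  gaps <- do.call(rbind, agg)
  if (any(gaps$n < 2L))
    warning("SD undefined for gap(s) covered by fewer than 2 subjects: ",
            paste(diskPairName(gaps$upper_level[gaps$n < 2L]), collapse = ", "))
  new("DiskTemplate", gaps = gaps)
}

#' Read / write a template as headered CSV
#'
#' Columns: \code{upper_level}, \code{lower_level}, \code{mean_mm},
#' \code{sd_mm}, \code{n}, one row per gap, rostral to caudal. The round
#' trip is lossless; files with missing columns, non-contiguous levels or
#' non-positive distances are rejected naming the offending row.
#'
#' @param path CSV path.
#' @param t a \linkS4class{DiskTemplate}.
#' @return \code{readDiskTemplate}: a \linkS4class{DiskTemplate}.
#' @export
readDiskTemplate <- function(path) {
  if (!file.exists(path)) stop("template file not found: ", path)
  g <- utils::read.csv(path)
  need <- c("upper_level", "lower_level", "mean_mm", "sd_mm", "n")
  missing <- setdiff(need, names(g))
  if (length(missing))
    stop("template file missing column(s): ", paste(missing, collapse = ", "))
  g <- g[need]
  bad <- which(g$lower_level != g$upper_level + 1 |
               !is.finite(g$mean_mm) | g$mean_mm <= 0)
  if (length(bad))
    stop(sprintf("invalid template row %d (levels %s/%s, distance %s)",
                 bad[1], g$upper_level[bad[1]], g$lower_level[bad[1]],
                 g$mean_mm[bad[1]]))
  if (nrow(g) > 1L) {
    jump <- which(diff(g$upper_level) != 1)
    if (length(jump))
      stop(sprintf("template rows %d-%d skip a level (%s then %s)",
                   jump[1], jump[1] + 1L, diskPairName(g$upper_level[jump[1]]),
                   diskPairName(g$upper_level[jump[1] + 1L])))
  }
  g$upper_level <- as.integer(g$upper_level)
  g$lower_level <- as.integer(g$lower_level)
  g$n <- as.integer(g$n)
  new("DiskTemplate", gaps = g)
}

#' @rdname readDiskTemplate
#' @export
writeDiskTemplate <- function(t, path) {
  stopifnot(is(t, "DiskTemplate"))
  utils::write.csv(t@gaps, path, row.names = FALSE)
  invisible(path)
}

#' Validate a template against anatomical expectations
#'
#' Reports (without rejecting) gaps that break the caudal-increase trend of
#' adult intervertebral distances, and gaps whose relative SD exceeds 20\% of
#' the mean — the same 20\% that bounds the local search range during
#' detection, so a larger spread would make the search window too narrow for
#' that gap's variability.
#'
#' @param t a \linkS4class{DiskTemplate}.
#' @param maxRelSd flagged relative SD threshold (default 0.2).
#' @return data.frame report with columns \code{gap}, \code{check},
#'   \code{message}; zero rows when nothing is flagged.
#' @export
validateTemplate <- function(t, maxRelSd = 0.2) {
  stopifnot(is(t, "DiskTemplate"))
  g <- t@gaps
  rep <- list()
  if (nrow(g) > 1L) {
    dec <- which(diff(g$mean_mm) <= 0)
    for (i in dec)
      rep[[length(rep) + 1L]] <- data.frame(
        gap = diskPairName(g$upper_level[i + 1L]), check = "caudal_increase",
        message = sprintf("mean %.1f mm does not exceed the %.1f mm of %s",
                          g$mean_mm[i + 1L], g$mean_mm[i],
                          diskPairName(g$upper_level[i])))
  }
  rel <- g$sd_mm / g$mean_mm
  high <- which(!is.na(rel) & rel > maxRelSd)
  for (i in high)
    rep[[length(rep) + 1L]] <- data.frame(
      gap = diskPairName(g$upper_level[i]), check = "relative_sd",
      message = sprintf("sd/mean = %.2f exceeds the %.2f search-range reference",
                        rel[i], maxRelSd))
  if (!length(rep))
    return(data.frame(gap = character(), check = character(),
                      message = character()))
  do.call(rbind, rep)
}
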