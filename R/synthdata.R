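#' Synthesize a histology-like slide image
#'
#' Generates a stained-tissue lookalike for exercising the tiler: elliptical
#' "cells" in hematoxylin purple and eosin pink scattered over a pale
#' background, plus Gaussian pixel noise. The texture exists to give JPEG
#' compression and downsampling something realistic to chew on; no
#' biological realism is claimed. Output is deterministic for fixed
#' parameters and seed.
#'
#' @param width,height image dimensions in pixels (>= 64).
#' @param nucleusDensity ellipses per megapixel (default 150).
#' @param radiusRange ellipse semi-axis range in pixels (default 4-12).
#' @param background RGB in [0,1]; default near-white with a faint pink
#'   cast, as on a brightfield scan.
#' @param palette list of RGB colours for the ellipses; default a
#'   hematoxylin/eosin purple-pink pair.
#' @param noiseSd per-channel Gaussian noise SD in intensity units; the
#'   default 0.005 is about one gray level of an 8-bit scan, the order of
#'   sensor noise in brightfield whole-slide scanner output.
#' @param seed integer seed.
#' @return raster array \code{[height, width, 3]} in [0,1].
#' @examples
#' img <- synthSlide(256, 192, seed = 1)
#' dim(img)
#' @export
synthSlide <- function(width, height, nucleusDensity = 150,
                       radiusRange = c(4, 12),
                       background = c(0.97, 0.94, 0.96),
                       palette = list(c(0.35, 0.20, 0.50),
                                      c(0.85, 0.50, 0.60)),
                       noiseSd = 0.005, seed = 1) {
  if (width < 64 || height < 64)
    stopInvalid("synthetic slides must be at least 64x64 pixels")
  withSeed(seed, {
    img <- array(rep(background, each = height * width),
                 dim = c(height, width, 3L))
    n <- round(nucleusDensity * width * height / 1e6)
    if (n > 0) {
      cx <- stats::runif(n, 1, width)
      cy <- stats::runif(n, 1, height)
      a <- stats::runif(n, radiusRange[1], radiusRange[2])
      b <- stats::runif(n, radiusRange[1], radiusRange[2])
      th <- stats::runif(n, 0, pi)
      col <- sample(length(palette), n, replace = TRUE)
      jit <- matrix(stats::runif(3 * n, -0.05, 0.05), ncol = 3)
      for (i in seq_len(n)) {
        r <- max(a[i], b[i])
        rows <- max(1, floor(cy[i] - r)):min(height, ceiling(cy[i] + r))
        cols <- max(1, floor(cx[i] - r)):min(width, ceiling(cx[i] + r))
        dy <- rows - cy[i]; dx <- cols - cx[i]
        # rotated-ellipse mask over the bounding box
        u <- outer(dy, dx, function(y, x)  x * cos(th[i]) + y * sin(th[i]))
        v <- outer(dy, dx, function(y, x) -x * sin(th[i]) + y * cos(th[i]))
        mask <- (u / a[i])^2 + (v / b[i])^2 <= 1
        rgb <- pmin(1, pmax(0, palette[[col[i]]] + jit[i, ]))
        for (ch in 1:3) {
          sl <- img[rows, cols, ch]
          sl[mask] <- rgb[ch]
          img[rows, cols, ch] <- sl
        }
      }
    }
    if (noiseSd > 0)
      img <- img + stats::rnorm(length(img), 0, noiseSd)
    img <- pmin(pmax(img, 0), 1)  # img first: pmin/pmax keep the 1st arg's dim
    round(img * 255) / 255        # quantize to the 8 bits a scanner delivers
  })
}

#' Synthesize a slide view log
#'
#' Emulates a month of student usage: each student's views arrive in
#' sessions of consecutive slide opens separated by dwell-time gaps, and
#' each session lands either inside the daily laboratory window (probability
#' \code{pInWindow}) or outside it, where \code{eveningShare} of the
#' out-of-lab mass sits in the evening (default 4 pm to midnight, echoing
#' observed usage). Dwell gaps are gamma distributed (shape 4) with the
#' requested mean. With \code{exactCounts} the generator instead emits
#' independent timestamps with exactly the requested in/out split -- the
#' fixture mode for share computations.
#'
#' @param nStudents number of students (default 164, a course cohort).
#' @param nSlides number of distinct slides viewed (default 300).
#' @param dateRange character \code{c(first, last)} dates (default a 4-week
#'   course block).
#' @param labWindow daily window \code{c("HH:MM", "HH:MM")}, half-open
#'   (default 10 am to noon).
#' @param pInWindow probability a session falls in the lab window
#'   (default 0.53, the observed in-lab share).
#' @param eveningShare share of out-of-window sessions in
#'   \code{eveningWindow} (default 0.773).
#' @param eveningWindow default \code{c("16:00", "24:00")}.
#' @param dwellMeanSec mean dwell per view in seconds (default 548,
#'   i.e. 9 min 8 s).
#' @param viewsPerStudent mean total views per student (default 79, about
#'   12,982 views across 164 students).
#' @param sessionSizeMean mean slides opened per session (default 21, the
#'   observed in-lab average). Sessions are placed so they fit inside their
#'   window when possible; an oversized session overflows forward in time.
#' @param seed integer seed.
#' @param exactCounts optional \code{c(in, out)} totals; switches to
#'   independent-timestamp fixture mode.
#' @param file optional CSV path; when given the log is also written in the
#'   format [loadViewlog()] reads.
#' @return \code{data.frame(user_id, slide_id, timestamp)}.
#' @examples
#' log <- synthViewlog(nStudents = 10, viewsPerStudent = 20, seed = 1)
#' windowShare(log)$in_pct
#' @export
synthViewlog <- function(nStudents = 164, nSlides = 300,
                         dateRange = c("2010-03-01", "2010-03-28"),
                         labWindow = c("10:00", "12:00"),
                         pInWindow = 0.53, eveningShare = 0.773,
                         eveningWindow = c("16:00", "24:00"),
                         dwellMeanSec = 548, viewsPerStudent = 79,
                         sessionSizeMean = 21, seed = 1,
                         exactCounts = NULL, file = NULL) {
  d0 <- as.Date(dateRange[1]); d1 <- as.Date(dateRange[2])
  if (is.na(d0) || is.na(d1) || d1 < d0) stopInvalid("invalid date range")
  ndays <- as.integer(d1 - d0) + 1L
  ws <- parseHM(labWindow[1]) * 60; we <- parseHM(labWindow[2]) * 60
  es <- parseHM(eveningWindow[1]) * 60; ee <- parseHM(eveningWindow[2]) * 60
  if (ws >= we) stopInvalid("invalid lab window")
  day0 <- as.POSIXct(paste(d0, "00:00:00"), tz = "UTC")

  log <- withSeed(seed, {
    if (!is.null(exactCounts)) {
      nin <- exactCounts[1]; nout <- exactCounts[2]
      # in-window: uniform over [ws, we); out: evening bump + the rest of
      # the day outside both windows
      tin <- stats::runif(nin, ws, we - 1)
      evening <- stats::runif(nout) < eveningShare
      tout <- numeric(nout)
      tout[evening] <- stats::runif(sum(evening), max(es, we), ee - 1)
      # remaining out-of-window mass: [0, ws) and [we, es)
      segs <- rbind(c(0, ws), c(we, es))
      segLen <- segs[, 2] - segs[, 1]
      pick <- sample(1:2, sum(!evening), replace = TRUE,
                     prob = segLen / sum(segLen))
      tout[!evening] <- segs[pick, 1] +
        stats::runif(sum(!evening)) * segLen[pick]
      tod <- c(tin, tout)
      n <- length(tod)
      days <- sample.int(ndays, n, replace = TRUE) - 1L
      data.frame(
        user_id = paste0("stu", sample.int(nStudents, n, replace = TRUE)),
        slide_id = paste0("s", sample.int(nSlides, n, replace = TRUE)),
        timestamp = day0 + days * 86400 + tod)
    } else {
      rows <- list()
      for (u in seq_len(nStudents)) {
        total <- max(1L, stats::rpois(1, viewsPerStudent))
        left <- total
        while (left > 0L) {
          size <- min(left, 1L + stats::rpois(1, max(0, sessionSizeMean - 1)))
          left <- left - size
          gaps <- if (size > 1)
            stats::rgamma(size - 1, shape = 4, scale = dwellMeanSec / 4)
            else numeric(0)
          dur <- sum(gaps)
          inlab <- stats::runif(1) < pInWindow
          if (inlab) {
            seg <- c(ws, we)
          } else if (stats::runif(1) < eveningShare) {
            seg <- c(max(es, we), ee)
          } else {
            segs <- rbind(c(0, ws), c(we, es))
            segLen <- segs[, 2] - segs[, 1]
            seg <- segs[sample(1:2, 1, prob = segLen / sum(segLen)), ]
          }
          start <- stats::runif(1, seg[1], max(seg[1] + 1, seg[2] - dur))
          day <- sample.int(ndays, 1) - 1L
          ts <- day0 + day * 86400 + start + cumsum(c(0, gaps))
          rows[[length(rows) + 1L]] <- data.frame(
            user_id = paste0("stu", u),
            slide_id = paste0("s", sample.int(nSlides, size, replace = TRUE)),
            timestamp = ts)
        }
      }
      do.call(rbind, rows)
    }
  })
  log <- log[order(log$user_id, log$timestamp), ]
  rownames(log) <- NULL
  if (!is.null(file)) {
    out <- data.frame(user_id = log$user_id, slide_id = log$slide_id,
                      timestamp = format(log$timestamp,
                                         "%Y-%m-%dT%H:%M:%S", tz = "UTC"))
    utils::write.csv(out, file, row.names = FALSE, quote = FALSE)
  }
  log
}

#' Synthesize an exam-score cohort
#'
#' Truncated-normal draws on a bounded score scale; for n of a hundred or
#' more the sample mean and SD land within sampling error of the targets,
#' so summaries of synthetic cohorts can be fed into [welchFromSummary()].
#'
#' @param mean,sd target score mean and SD.
#' @param n cohort size (>= 2).
#' @param bounds score bounds, default \code{c(0, 100)}.
#' @param seed integer seed.
#' @return numeric vector of n scores.
#' @examples
#' summary(synthCohort(81.8, 11.9, 164, seed = 3))
#' @export
synthCohort <- function(mean, sd, n, bounds = c(0, 100), seed = 1) {
  if (n < 2) stopInvalid("cohort size must be >= 2")
  if (bounds[1] >= bounds[2]) stopInvalid("invalid score bounds")
  withSeed(seed, {
    out <- numeric(0)
    while (length(out) < n) {
      x <- stats::rnorm(2 * (n - length(out)) + 10, mean, sd)
      out <- c(out, x[x >= bounds[1] & x <= bounds[2]])
    }
    out[seq_len(n)]
  })
}

#' Synthesize a populated annotation store
#'
#' Builds an [AnnotationStore-class] with the requested numbers of faculty
#' and student pushpin markers spread over \code{nSlides} slides at random
#' normalized positions and creation zooms -- the fixture behind authorship
#' and voting analytics. Defaults mirror a deployed course's annotation
#' census (163 faculty and 458 student markers on 126 slides).
#'
#' @param nFaculty,nStudent marker counts by author role.
#' @param nSlides number of distinct slides annotated.
#' @param zMax maximum creation zoom (default 6).
#' @param seed integer seed.
#' @return an [AnnotationStore-class].
#' @export
synthMarkers <- function(nFaculty = 163, nStudent = 458, nSlides = 126,
                         zMax = 6, seed = 1) {
  withSeed(seed, {
    st <- AnnotationStore()
    n <- nFaculty + nStudent
    role <- sample(rep(c("faculty", "student"), c(nFaculty, nStudent)))
    slide <- paste0("s", sample.int(nSlides, n, replace = TRUE))
    for (i in seq_len(n)) {
      author <- if (role[i] == "faculty")
        paste0("fac", sample.int(14, 1)) else
        paste0("stu", sample.int(164, 1))
      st <- addMarker(st, author, role[i], slide[i], "pushpin",
                      stats::runif(1), stats::runif(1),
                      sample.int(zMax + 1L, 1L) - 1L,
                      title = paste0("structure-", i))
    }
    st
  })
}
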