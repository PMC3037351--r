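# Shared fixtures and independent oracles, built in code at test time.

# Brute-force tile-count oracle: repeatedly halve with ceiling until the
# whole level fits one tile, summing ceil(w/ts) * ceil(h/ts) per level.
# Independent of planPyramid's arithmetic.
bruteTileCount <- function(w, h, ts = 256) {
  total <- 0
  repeat {
    total <- total + ceiling(w / ts) * ceiling(h / ts)
    if (w <= ts && h <= ts) break
    w <- ceiling(w / 2); h <- ceiling(h / 2)
  }
  total
}

# Loop-based 2x area-mean downsampler (independent of downsample2x).
bruteDownsample <- function(img) {
  h <- dim(img)[1]; w <- dim(img)[2]
  nh <- ceiling(h / 2); nw <- ceiling(w / 2)
  out <- array(0, dim = c(nh, nw, 3))
  for (i in seq_len(nh)) for (j in seq_len(nw)) {
    rows <- (2 * i - 1):min(2 * i, h)
    cols <- (2 * j - 1):min(2 * j, w)
    for (ch in 1:3) out[i, j, ch] <- mean(img[rows, cols, ch])
  }
  out
}

# A small slide store with a mix of teaching and exam slides.
fixtureSlideStore <- function() {
  st <- SlideStore()
  st <- addSlide(st, "s1", "Kidney, radial section",
                 tissue_organ = "kidney", stain = "H&E")
  st <- addSlide(st, "s2", "Jejunum", tissue_organ = "small intestine",
                 stain = "H&E")
  st <- addSlide(st, "s3", "Kidney cortex", tissue_organ = "kidney",
                 stain = "PAS")
  st <- addSlide(st, "e1", "Exam: unknown A", access_tier = "exam",
                 tissue_organ = "kidney")
  st <- addSlide(st, "e2", "Exam: unknown B", access_tier = "exam")
  st
}

# An approved two-question exam over small pools.
fixtureExam <- function(poolSizes = c(3, 2),
                        points = rep(1, length(poolSizes))) {
  pools <- lapply(seq_along(poolSizes), function(i)
    paste0("e", i, letters[seq_len(poolSizes[i])]))
  ex <- newExam("mid", data.frame(
    question_id = paste0("q", seq_along(poolSizes)),
    tissue_label = paste0("tissue", seq_along(poolSizes)),
    points = points, pool = I(pools)))
  approveExam(ex)
}

# View log with hand-picked timestamps (one user) for boundary checks.
eventsAt <- function(times, user = "u1", slide = "s1",
                     date = "2010-03-02") {
  data.frame(user_id = user, slide_id = slide,
             timestamp = as.POSIXct(paste(date, times), tz = "UTC"))
}
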