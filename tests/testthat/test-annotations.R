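freshMarker <- function(st = AnnotationStore(), author = "stuA",
                        role = "student", slide = "s1") {
  st <- addMarker(st, author, role, slide, "pushpin", 0.5, 0.5, 3,
                  title = "glomerulus")
  list(store = st, id = lastMarkerId(st))
}

test_that("markers keep position, zoom and image-sequence order", {
  st <- AnnotationStore()
  st <- addMarker(st, "fac1", "faculty", "s1", "pushpin", 0.25, 0.75, 4,
                  title = "podocyte", zMax = 6)
  m <- getMarker(st, lastMarkerId(st))
  expect_equal(c(m$x_norm, m$y_norm), c(0.25, 0.75))
  expect_identical(m$created_zoom, 4L)
  expect_identical(m$author_role, "faculty")

  seq3 <- data.frame(image_ref = c("a.png", "b.png", "c.png"),
                     caption = c("first", "second", "third"))
  st <- addMarker(st, "stu1", "student", "s1", "image", 0.1, 0.1, 2,
                  image_sequence = seq3)
  got <- attr(getMarker(st, lastMarkerId(st)), "image_sequence")
  expect_identical(got$caption, c("first", "second", "third"))
})

test_that("marker validation rejects bad positions, zooms and payloads", {
  st <- AnnotationStore()
  expect_error(addMarker(st, "u", "student", "s1", "pushpin", 1.2, 0.5, 0,
                         title = "x"), "\\[0,1\\]")
  expect_error(addMarker(st, "u", "student", "s1", "pushpin", 0.5, 0.5, 9,
                         title = "x", zMax = 6), "maximum zoom")
  expect_error(addMarker(st, "u", "student", "s1", "pushpin", 0.5, 0.5, 0,
                         title = "  "), "non-empty title")
  expect_error(addMarker(st, "u", "student", "s1", "image", 0.5, 0.5, 0),
               "image_ref")
})

test_that("six distinct down votes remove a marker; five do not", {
  fm <- freshMarker()
  st <- fm$store
  for (v in paste0("v", 1:5)) st <- castVote(st, v, fm$id, "down")
  expect_identical(markerScore(st, fm$id), -5L)
  expect_true(getMarker(st, fm$id)$visible)          # strict inequality
  st <- castVote(st, "v6", fm$id, "down")
  expect_identical(markerScore(st, fm$id), -6L)
  expect_false(getMarker(st, fm$id)$visible)
  # removed marker remains visible to its author only
  expect_true(fm$id %in% visibleMarkers(st, "s1", viewer = "stuA")$marker_id)
  expect_false(fm$id %in% visibleMarkers(st, "s1", viewer = "v1")$marker_id)
  # an up vote restores visibility (pure function of score)
  st <- castVote(st, "v7", fm$id, "up")
  expect_true(getMarker(st, fm$id)$visible)
})

test_that("revoting replaces the prior vote instead of stacking", {
  fm <- freshMarker()
  st <- castVote(fm$store, "u1", fm$id, "down")
  st <- castVote(st, "u1", fm$id, "down")
  st <- castVote(st, "u1", fm$id, "up")
  expect_identical(markerScore(st, fm$id), 1L)
  expect_error(castVote(st, "u1", "m999", "up"), "unknown marker")
})

test_that("score always equals up-minus-down over live votes (fuzzed)", {
  set.seed(505)
  for (rep in 1:5) {
    st <- AnnotationStore()
    nm <- 6
    for (i in seq_len(nm))
      st <- addMarker(st, paste0("a", i), "student", "s1", "pushpin",
                      runif(1), runif(1), 0, title = paste("m", i))
    ids <- paste0("m", seq_len(nm))
    voters <- paste0("v", 1:10)
    for (k in 1:120)
      st <- castVote(st, sample(voters, 1), sample(ids, 1),
                     sample(c("up", "down"), 1))
    vt <- st@votes
    for (id in ids) {
      live <- vt[vt$marker_id == id, ]
      expect_lte(max(table(live$voter_id), 0), 1)   # one live vote per voter
      expect_identical(markerScore(st, id),
                       as.integer(sum(live$direction == "up") -
                                  sum(live$direction == "down")))
      expect_identical(getMarker(st, id)$visible, markerScore(st, id) >= -5L)
    }
  }
})

test_that("marker lists order by score, then creation time, then id", {
  st <- AnnotationStore()
  for (i in 1:4)
    st <- addMarker(st, "a", "student", "s1", "pushpin", 0.5, 0.5, 0,
                    title = paste("m", i))
  for (v in paste0("v", 1:3)) st <- castVote(st, v, "m2", "up")
  st <- castVote(st, "v1", "m4", "down")
  st <- castVote(st, "v1", "m3", "up")
  got <- visibleMarkers(st, "s1")$marker_id
  expect_identical(got, c("m2", "m3", "m1", "m4"))   # 3, 1, 0, -1
  # m1 and the tie at score 0: earlier creation first
  st2 <- castVote(st, "v2", "m4", "up")              # m4 back to 0
  got2 <- visibleMarkers(st2, "s1")$marker_id
  expect_identical(got2, c("m2", "m3", "m1", "m4"))
})

test_that("tags normalize, collapse duplicates and weight the cloud", {
  st <- AnnotationStore()
  st <- addTag(st, "u1", "s1", "  Kidney ")
  st <- addTag(st, "u2", "s1", "kidney")
  st <- addTag(st, "u1", "s1", "kidney")       # duplicate triple collapses
  cloud <- tagCloud(st)
  expect_identical(nrow(cloud), 1L)
  expect_identical(cloud$count, 2L)
  expect_identical(cloud$weight, 5L)           # its own maximum
  expect_error(addTag(st, "u1", "s1", "   "), "non-empty")
  expect_identical(searchTags(st, "KIDNEY  "), "s1")

  # counts {10, 3, 1} bucket to weights {5, 3, 2}
  st2 <- AnnotationStore()
  for (u in paste0("u", 1:10)) st2 <- addTag(st2, u, "s1", "cortex")
  for (u in paste0("u", 1:3))  st2 <- addTag(st2, u, "s2", "medulla")
  st2 <- addTag(st2, "u1", "s3", "rare")
  cl <- tagCloud(st2)
  expect_identical(cl$text, c("cortex", "medulla", "rare"))
  expect_identical(cl$weight, c(5L, 3L, 2L))
})

test_that("cloud weights are monotone in count and stay within 1..5", {
  set.seed(99)
  st <- AnnotationStore()
  for (i in 1:30) {
    term <- paste0("t", sample(1:8, 1))
    st <- addTag(st, paste0("u", sample(1:40, 1)),
                 paste0("s", sample(1:5, 1)), term)
  }
  cl <- tagCloud(st)
  expect_true(all(cl$weight >= 1 & cl$weight <= 5))
  o <- order(cl$count)
  expect_true(all(diff(cl$weight[o]) >= 0))
})

test_that("yearly reset removes student markers and votes, keeps faculty", {
  st <- synthMarkers(nFaculty = 163, nStudent = 458, seed = 8)
  ids <- st@markers$marker_id
  set.seed(8)
  for (k in 1:200)
    st <- castVote(st, paste0("v", sample(1:50, 1)), sample(ids, 1),
                   sample(c("up", "down"), 1))
  res <- resetCourse(st, hideFaculty = TRUE)
  expect_identical(res$removed_markers, 458L)
  expect_identical(res$retained_faculty, 163L)
  after <- res$store
  expect_identical(sum(after@markers$author_role == "student"), 0L)
  expect_identical(nrow(after@markers), 163L)
  # no dangling votes
  expect_true(all(after@votes$marker_id %in% after@markers$marker_id))
  # faculty markers are hidden until restored, so slides read as unknowns
  someSlide <- after@markers$slide_id[1]
  expect_identical(nrow(visibleMarkers(after, someSlide)), 0L)
  shown <- setFacultyHidden(after, FALSE)
  expect_gt(nrow(visibleMarkers(shown, someSlide)), 0L)
  # resetting an empty store is a no-op
  empty <- resetCourse(AnnotationStore())
  expect_identical(empty$removed_markers, 0L)
})

test_that("polling deltas are empty until a change and replay to full state", {
  st <- AnnotationStore()
  st <- addMarker(st, "a", "student", "s1", "pushpin", 0.5, 0.5, 0,
                  title = "m")
  d1 <- changedSince(st, "s1", 0L)
  expect_identical(nrow(d1$created), 1L)
  d2 <- changedSince(st, "s1", d1$revision)
  expect_identical(nrow(d2$created) + nrow(d2$updated) + length(d2$removed),
                   0L)
  st <- castVote(st, "v1", "m1", "up")
  d3 <- changedSince(st, "s1", d1$revision)
  expect_identical(d3$updated$marker_id, "m1")
  expect_identical(d3$updated$score, 1L)
})

test_that("replaying random deltas reproduces the final marker state", {
  set.seed(2024)
  for (rep in 1:3) {
    st <- AnnotationStore()
    shadow <- NULL   # marker table reconstructed from deltas only
    since <- 0L
    applyDelta <- function(shadow, d) {
      if (nrow(d$created)) shadow <- rbind(shadow, d$created)
      if (nrow(d$updated)) {
        i <- match(d$updated$marker_id, shadow$marker_id)
        shadow[i, ] <- d$updated
      }
      if (length(d$removed))
        shadow <- shadow[!(shadow$marker_id %in% d$removed), , drop = FALSE]
      shadow
    }
    for (step in 1:40) {
      op <- sample(c("add", "vote", "reset"), 1, prob = c(0.5, 0.45, 0.05))
      if (op == "add" || nrow(st@markers) == 0) {
        st <- addMarker(st, paste0("u", sample(1:5, 1)),
                        sample(c("student", "faculty"), 1), "s1", "pushpin",
                        runif(1), runif(1), 0, title = "x")
      } else if (op == "vote") {
        st <- castVote(st, paste0("v", sample(1:8, 1)),
                       sample(st@markers$marker_id, 1),
                       sample(c("up", "down"), 1))
      } else {
        st <- resetCourse(st)$store
      }
      if (runif(1) < 0.4) {   # poll at irregular intervals
        d <- changedSince(st, "s1", since)
        shadow <- applyDelta(shadow, d)
        since <- d$revision
      }
    }
    d <- changedSince(st, "s1", since)
    shadow <- applyDelta(shadow, d)
    truth <- st@markers
    attr(truth, "removal_threshold") <- NULL
    o1 <- order(shadow$marker_id); o2 <- order(truth$marker_id)
    expect_equal(shadow[o1, ], truth[o2, ], ignore_attr = TRUE)
  }
})

test_that("annotation stores round-trip through JSON lines", {
  st <- AnnotationStore()
  st <- addMarker(st, "fac1", "faculty", "s1", "pushpin", 0.2, 0.3, 2,
                  title = "artery")
  st <- addMarker(st, "stu1", "student", "s2", "image", 0.6, 0.6, 1,
                  image_sequence = data.frame(image_ref = "x.png",
                                              caption = "cap"))
  st <- castVote(st, "v1", "m1", "up")
  st <- addTag(st, "u1", "s1", "Vessel")
  f <- withr::local_tempfile(fileext = ".jsonl")
  writeAnnotationStore(st, f)
  st2 <- readAnnotationStore(f)
  expect_identical(nrow(st2@markers), 2L)
  expect_identical(markerScore(st2, "m1"), 1L)
  expect_identical(tagCloud(st2)$text, "vessel")
  expect_identical(attr(getMarker(st2, "m2"), "image_sequence")$caption,
                   "cap")
})
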