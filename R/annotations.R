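VOTE_REMOVAL_THRESHOLD <- -5L

#' AnnotationStore: markers, votes and tags for a slide collection
#'
#' The collaborative core of a virtual-microscope deployment. Any user places
#' \emph{markers} on slides -- pushpins (title + description) or embedded
#' image sequences with captions -- at a normalized position and with the
#' zoom level at which they were created, so a viewer can centre and zoom
#' back to the author's view. Peers vote markers up or down; a marker whose
#' cumulative score drops below -5 is automatically removed and remains
#' visible only to its author. Free-text tags build a folksonomy rendered as
#' a weighted tag cloud. All updates are functional: mutators return the
#' updated store. Every change bumps an integer store revision, which drives
#' the polling synchronisation contract of [changedSince()].
#'
#' @slot markers one row per marker: id, slide, author and role, kind,
#'   normalized position, creation zoom, title/description, vote score,
#'   creation order and revision bookkeeping, and a \code{reset_hidden} flag
#'   used to present faculty markers anew as unknowns after a course reset.
#' @slot imageSeqs named list (by marker id) of
#'   \code{data.frame(image_ref, caption)} for image markers.
#' @slot votes live votes, at most one per (voter, marker).
#' @slot tags normalized free-text tags, one row per (slide, user, text).
#' @slot tombstones markers deleted since the store was created, with the
#'   revision at which each was removed.
#' @slot revision monotone change counter ("server timestamp" for polling).
#' @slot nextId counter used to mint marker ids \code{m1, m2, ...}.
#' @seealso [addMarker()], [castVote()], [visibleMarkers()], [tagCloud()],
#'   [resetCourse()], [changedSince()]
#' @export
setClass("AnnotationStore",
  representation(
    markers    = "data.frame",
    imageSeqs  = "list",
    votes      = "data.frame",
    tags       = "data.frame",
    tombstones = "data.frame",
    revision   = "integer",
    nextId     = "integer"
  )
)

setValidity("AnnotationStore", function(object) {
  mk <- object@markers
  if (nrow(mk)) {
    if (anyDuplicated(mk$marker_id)) return("duplicate marker ids")
    if (any(mk$x_norm < 0 | mk$x_norm > 1 | mk$y_norm < 0 | mk$y_norm > 1))
      return("marker positions must lie in [0,1]^2")
    if (!all(mk$author_role %in% c("faculty", "student")))
      return("author_role must be 'faculty' or 'student'")
    if (!all(mk$kind %in% c("pushpin", "image")))
      return("kind must be 'pushpin' or 'image'")
  }
  vt <- object@votes
  if (nrow(vt)) {
    if (anyDuplicated(vt[c("voter_id", "marker_id")]))
      return("at most one live vote per (voter, marker)")
    if (!all(vt$marker_id %in% mk$marker_id))
      return("votes reference unknown markers")
    if (!all(vt$direction %in% c("up", "down")))
      return("vote direction must be 'up' or 'down'")
  }
  TRUE
})

emptyMarkers <- function() data.frame(
  marker_id = character(0), slide_id = character(0),
  author_id = character(0), author_role = character(0),
  kind = character(0), x_norm = numeric(0), y_norm = numeric(0),
  created_zoom = integer(0), title = character(0),
  description = character(0), score = integer(0),
  created_at = numeric(0), created_rev = integer(0),
  updated_rev = integer(0), reset_hidden = logical(0))

#' Create an empty annotation store
#'
#' @param removalThreshold score below which a marker is auto-removed
#'   (default -5, the deployed value).
#' @return an [AnnotationStore-class].
#' @examples
#' st <- AnnotationStore()
#' st <- addMarker(st, "fac1", "faculty", "s1", "pushpin", 0.5, 0.5, 3,
#'                 title = "Glomerulus")
#' visibleMarkers(st, "s1")$title
#' @export
AnnotationStore <- function(removalThreshold = VOTE_REMOVAL_THRESHOLD) {
  st <- new("AnnotationStore",
    markers = emptyMarkers(),
    imageSeqs = list(),
    votes = data.frame(voter_id = character(0), marker_id = character(0),
                       direction = character(0), cast_rev = integer(0)),
    tags = data.frame(slide_id = character(0), user_id = character(0),
                      text = character(0)),
    tombstones = data.frame(marker_id = character(0), slide_id = character(0),
                            deleted_rev = integer(0)),
    revision = 0L, nextId = 1L)
  attr(st@markers, "removal_threshold") <- as.integer(removalThreshold)
  st
}

removalThreshold <- function(store) {
  th <- attr(store@markers, "removal_threshold")
  if (is.null(th)) VOTE_REMOVAL_THRESHOLD else th
}

#' Is a marker with this score visible?
#'
#' Visibility is a pure function of the cumulative vote score: a marker is
#' hidden (auto-removed, visible only to its author) exactly when its score
#' is strictly below the removal threshold. A removed marker whose score
#' later recovers to the threshold or above becomes visible again.
#'
#' @param score integer vote score(s).
#' @param threshold removal threshold (default -5).
#' @return logical vector.
#' @export
markerVisible <- function(score, threshold = VOTE_REMOVAL_THRESHOLD) {
  score >= threshold
}

setMethod("show", "AnnotationStore", function(object) {
  mk <- object@markers
  cat(sprintf(
    "AnnotationStore: %d markers (%d faculty, %d student), %d votes, %d tags, rev %d\n",
    nrow(mk), sum(mk$author_role == "faculty"),
    sum(mk$author_role == "student"), nrow(object@votes),
    nrow(object@tags), object@revision))
  invisible(NULL)
})

#' Place a marker on a slide
#'
#' Positions are normalized to the full-resolution image ([0,1] from the
#' top-left corner) so they are independent of zoom and tile size;
#' \code{created_zoom} records the zoom level the author was viewing, which
#' the click-to-zoom behaviour restores. Pushpin markers need a non-empty
#' title; image markers need at least one (image, caption) pair, whose order
#' is preserved.
#'
#' @param store an [AnnotationStore-class].
#' @param author_id,author_role who placed the marker; faculty markers are
#'   rendered distinctly by clients.
#' @param slide_id slide the marker belongs to.
#' @param kind \code{"pushpin"} or \code{"image"}.
#' @param x_norm,y_norm position in [0,1], origin top-left.
#' @param created_zoom zoom level at creation (0..the slide's zMax).
#' @param title,description pushpin text.
#' @param image_sequence \code{data.frame(image_ref, caption)} for image
#'   markers.
#' @param zMax optional maximum zoom of the slide, used to validate
#'   \code{created_zoom}.
#' @param at optional creation time (numeric or POSIXct); defaults to the
#'   store revision so creation order is always recovered.
#' @return the updated store; the new marker's id is
#'   \code{lastMarkerId(store)}.
#' @export
addMarker <- function(store, author_id, author_role, slide_id,
                      kind = c("pushpin", "image"), x_norm, y_norm,
                      created_zoom, title = "", description = "",
                      image_sequence = NULL, zMax = NULL, at = NULL) {
  stopifnot(is(store, "AnnotationStore"))
  kind <- match.arg(kind)
  author_role <- match.arg(author_role, c("faculty", "student"))
  if (!is.numeric(x_norm) || !is.numeric(y_norm) ||
      x_norm < 0 || x_norm > 1 || y_norm < 0 || y_norm > 1)
    stopInvalid("marker position must lie in [0,1]^2")
  created_zoom <- as.integer(created_zoom)
  if (is.na(created_zoom) || created_zoom < 0L)
    stopInvalid("created_zoom must be a non-negative integer")
  if (!is.null(zMax) && created_zoom > zMax)
    stopInvalid("created_zoom exceeds the slide's maximum zoom level")
  if (kind == "pushpin" && !nzchar(trimws(title)))
    stopInvalid("pushpin markers require a non-empty title")
  if (kind == "image") {
    if (is.null(image_sequence) || NROW(image_sequence) < 1L ||
        !all(c("image_ref", "caption") %in% names(image_sequence)))
      stopInvalid(
        "image markers require >= 1 (image_ref, caption) pair")
  }
  rev <- store@revision + 1L
  id <- paste0("m", store@nextId)
  row <- data.frame(
    marker_id = id, slide_id = slide_id, author_id = author_id,
    author_role = author_role, kind = kind, x_norm = x_norm, y_norm = y_norm,
    created_zoom = created_zoom, title = title, description = description,
    score = 0L,
    created_at = if (is.null(at)) as.numeric(rev) else as.numeric(at),
    created_rev = rev, updated_rev = rev, reset_hidden = FALSE)
  th <- removalThreshold(store)
  store@markers <- rbind(store@markers, row)
  attr(store@markers, "removal_threshold") <- th
  if (kind == "image")
    store@imageSeqs[[id]] <- as.data.frame(image_sequence)
  store@revision <- rev
  store@nextId <- store@nextId + 1L
  validObject(store)
  store
}

#' @rdname addMarker
#' @return \code{lastMarkerId} returns the id of the most recently added
#'   marker.
#' @export
lastMarkerId <- function(store) {
  stopifnot(is(store, "AnnotationStore"))
  if (store@nextId == 1L) stop("no markers have been added", call. = FALSE)
  paste0("m", store@nextId - 1L)
}

#' @rdname addMarker
#' @param marker_id marker to look up.
#' @return \code{getMarker} returns the one-row marker record with a
#'   \code{visible} column and, for image markers, an \code{image_sequence}
#'   attribute.
#' @export
getMarker <- function(store, marker_id) {
  stopifnot(is(store, "AnnotationStore"))
  i <- match(marker_id, store@markers$marker_id)
  if (is.na(i)) stop("unknown marker ", sQuote(marker_id), call. = FALSE)
  rec <- store@markers[i, , drop = FALSE]
  rec$visible <- markerVisible(rec$score, removalThreshold(store))
  rownames(rec) <- NULL
  if (rec$kind == "image")
    attr(rec, "image_sequence") <- store@imageSeqs[[marker_id]]
  rec
}

#' Vote a marker up or down
#'
#' Each user holds at most one live vote per marker; voting again replaces
#' the earlier vote (so a single user can never push a marker below the
#' removal threshold alone). The marker's score is recomputed over the live
#' votes of distinct voters and its visibility re-evaluated.
#'
#' @inheritParams addMarker
#' @param voter_id who votes (authors may vote on their own markers).
#' @param marker_id target marker.
#' @param direction \code{"up"} or \code{"down"}.
#' @return the updated store; the new score is
#'   \code{markerScore(store, marker_id)}.
#' @export
castVote <- function(store, voter_id, marker_id,
                     direction = c("up", "down")) {
  stopifnot(is(store, "AnnotationStore"))
  direction <- match.arg(direction)
  i <- match(marker_id, store@markers$marker_id)
  if (is.na(i)) stop("unknown marker ", sQuote(marker_id), call. = FALSE)
  rev <- store@revision + 1L
  vt <- store@votes
  vt <- vt[!(vt$voter_id == voter_id & vt$marker_id == marker_id), ,
           drop = FALSE]
  vt <- rbind(vt, data.frame(voter_id = voter_id, marker_id = marker_id,
                             direction = direction, cast_rev = rev))
  store@votes <- vt
  live <- vt[vt$marker_id == marker_id, ]
  th <- removalThreshold(store)
  store@markers$score[i] <-
    sum(live$direction == "up") - sum(live$direction == "down")
  store@markers$updated_rev[i] <- rev
  attr(store@markers, "removal_threshold") <- th
  store@revision <- rev
  store
}

#' @rdname castVote
#' @return \code{markerScore} returns the current integer score.
#' @export
markerScore <- function(store, marker_id) {
  getMarker(store, marker_id)$score
}

#' List a slide's markers in priority order
#'
#' Returns every visible marker on the slide, plus the viewer's own
#' auto-removed markers (hidden markers stay visible to their author).
#' Markers are ordered by score descending -- relative score determines
#' priority in the marker sidebar -- with ties broken by creation time
#' ascending, then marker id.
#'
#' @inheritParams addMarker
#' @param viewer optional viewer user id; enables the author-only view of
#'   removed markers.
#' @return \code{data.frame} of markers with a \code{visible} column.
#' @export
visibleMarkers <- function(store, slide_id, viewer = NULL) {
  stopifnot(is(store, "AnnotationStore"))
  mk <- store@markers[store@markers$slide_id == slide_id, , drop = FALSE]
  mk$visible <- markerVisible(mk$score, removalThreshold(store))
  keep <- (mk$visible | (!is.null(viewer) & mk$author_id %in% viewer)) &
    !mk$reset_hidden
  mk <- mk[keep, , drop = FALSE]
  mk <- mk[order(-mk$score, mk$created_at, mk$marker_id), , drop = FALSE]
  rownames(mk) <- NULL
  mk
}

# --- tags ------------------------------------------------------------------

normalizeTag <- function(text) {
  gsub("\\s+", " ", trimws(tolower(text)))
}

#' Tag a slide with a free-text term
#'
#' Tags are normalized (lower case, trimmed, internal whitespace collapsed)
#' and duplicate (slide, user, text) triples collapse to one, so the same
#' term from the same user counts once per slide.
#'
#' @inheritParams addMarker
#' @param user_id who tags.
#' @param text free-text term (non-empty after normalization).
#' @return the updated store.
#' @export
addTag <- function(store, user_id, slide_id, text) {
  stopifnot(is(store, "AnnotationStore"))
  norm <- normalizeTag(text)
  if (!nzchar(norm)) stopInvalid("tag must be non-empty after normalization")
  tg <- store@tags
  if (!any(tg$slide_id == slide_id & tg$user_id == user_id & tg$text == norm))
    store@tags <- rbind(tg, data.frame(slide_id = slide_id,
                                       user_id = user_id, text = norm))
  store
}

#' The tag cloud: term counts with log-scaled weight buckets
#'
#' Counts each normalized tag across all slides and assigns a prominence
#' bucket \code{weight = 1 + floor(4 * ln(1 + count) / ln(1 + max_count))},
#' clamped to [1, 5], so the most frequent tag always gets weight 5 and
#' weights grow logarithmically -- the usual folksonomy rendering rule.
#'
#' @inheritParams addMarker
#' @return \code{data.frame(text, count, weight)} sorted by count descending,
#'   then text.
#' @export
tagCloud <- function(store) {
  stopifnot(is(store, "AnnotationStore"))
  if (!nrow(store@tags))
    return(data.frame(text = character(0), count = integer(0),
                      weight = integer(0)))
  counts <- as.data.frame(table(text = store@tags$text),
                          stringsAsFactors = FALSE)
  names(counts)[2] <- "count"
  mx <- max(counts$count)
  counts$weight <- pmin(5L, pmax(1L, as.integer(
    1 + floor(4 * log1p(counts$count) / log1p(mx)))))
  counts <- counts[order(-counts$count, counts$text), ]
  rownames(counts) <- NULL
  counts
}

#' @rdname addTag
#' @param text optional normalized term to filter on.
#' @return \code{searchTags} returns slide ids carrying the term.
#' @export
searchTags <- function(store, text) {
  stopifnot(is(store, "AnnotationStore"))
  norm <- normalizeTag(text)
  sort(unique(store@tags$slide_id[store@tags$text == norm]))
}

# --- yearly reset ----------------------------------------------------------

#' Reset the store for a new course year
#'
#' Removes every student-authored marker together with its votes (no
#' dangling references remain), so slides can be presented anew as unknowns
#' to the incoming class. Faculty markers are retained; with
#' \code{hideFaculty = TRUE} they are bulk-hidden and can be restored with
#' \code{setFacultyHidden(store, FALSE)}.
#'
#' @inheritParams addMarker
#' @param hideFaculty also hide (not delete) faculty markers.
#' @return list with elements \code{store} (the updated store),
#'   \code{removed_markers}, \code{removed_votes} and
#'   \code{retained_faculty}.
#' @export
resetCourse <- function(store, hideFaculty = FALSE) {
  stopifnot(is(store, "AnnotationStore"))
  mk <- store@markers
  gone <- mk$marker_id[mk$author_role == "student"]
  rev <- store@revision + 1L
  th <- removalThreshold(store)
  removedVotes <- sum(store@votes$marker_id %in% gone)
  if (length(gone)) {
    store@tombstones <- rbind(store@tombstones, data.frame(
      marker_id = gone, slide_id = mk$slide_id[match(gone, mk$marker_id)],
      deleted_rev = rev))
    store@markers <- mk[!(mk$marker_id %in% gone), , drop = FALSE]
    store@votes <- store@votes[!(store@votes$marker_id %in% gone), ,
                               drop = FALSE]
    store@imageSeqs[gone] <- NULL
  }
  if (hideFaculty && nrow(store@markers)) {
    store@markers$reset_hidden <- TRUE
    store@markers$updated_rev <- rev
  }
  attr(store@markers, "removal_threshold") <- th
  store@revision <- rev
  list(store = store, removed_markers = length(gone),
       removed_votes = removedVotes,
       retained_faculty = sum(store@markers$author_role == "faculty"))
}

#' @rdname resetCourse
#' @param hidden logical; hide or unhide all faculty markers.
#' @export
setFacultyHidden <- function(store, hidden) {
  stopifnot(is(store, "AnnotationStore"))
  i <- store@markers$author_role == "faculty"
  if (any(i)) {
    rev <- store@revision + 1L
    th <- removalThreshold(store)
    store@markers$reset_hidden[i] <- hidden
    store@markers$updated_rev[i] <- rev
    attr(store@markers, "removal_threshold") <- th
    store@revision <- rev
  }
  store
}

# --- change synchronisation ------------------------------------------------

#' Poll for annotation changes since a revision
#'
#' The auto-refresh contract used to synchronise annotation data across
#' browsers during collaborative sessions: a client remembers the
#' \code{revision} returned by its last poll and asks for everything newer.
#' Polling again with the returned revision yields an empty delta until a
#' change occurs, and applying deltas in order reproduces the full marker
#' state.
#'
#' @inheritParams addMarker
#' @param slide_id optional slide filter; \code{NULL} polls the whole store.
#' @param since revision of the previous poll (0 for a full snapshot).
#' @return list with \code{created} and \code{updated} marker tables,
#'   \code{removed} marker ids, and the current \code{revision} to use for
#'   the next poll.
#' @export
changedSince <- function(store, slide_id = NULL, since = 0L) {
  stopifnot(is(store, "AnnotationStore"))
  mk <- store@markers
  tb <- store@tombstones
  if (!is.null(slide_id)) {
    mk <- mk[mk$slide_id == slide_id, , drop = FALSE]
    tb <- tb[tb$slide_id == slide_id, , drop = FALSE]
  }
  created <- mk[mk$created_rev > since, , drop = FALSE]
  updated <- mk[mk$updated_rev > since & mk$created_rev <= since, ,
                drop = FALSE]
  removed <- tb$marker_id[tb$deleted_rev > since]
  rownames(created) <- rownames(updated) <- NULL
  list(created = created, updated = updated, removed = removed,
       revision = store@revision)
}

# --- import / export -------------------------------------------------------

#' Read and write annotation stores as JSON lines
#'
#' Markers (with any image sequences inline), votes and tags are written one
#' JSON object per line, tagged by a \code{record} field.
#'
#' @param store an [AnnotationStore-class].
#' @param path file to write / read.
#' @return \code{writeAnnotationStore} returns \code{path} invisibly;
#'   \code{readAnnotationStore} returns the store. Revision bookkeeping is
#'   rebuilt on read, so polling state does not survive export.
#' @export
writeAnnotationStore <- function(store, path) {
  stopifnot(is(store, "AnnotationStore"))
  mk <- store@markers
  lines <- vapply(seq_len(nrow(mk)), function(i) {
    obj <- c(record = "marker", as.list(mk[i, c(
      "marker_id", "slide_id", "author_id", "author_role", "kind",
      "x_norm", "y_norm", "created_zoom", "title", "description",
      "created_at")]))
    seq <- store@imageSeqs[[mk$marker_id[i]]]
    if (!is.null(seq)) obj$image_sequence <- seq
    as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
  }, "")
  vt <- store@votes
  vlines <- vapply(seq_len(nrow(vt)), function(i)
    as.character(jsonlite::toJSON(
      c(record = "vote", as.list(vt[i, c("voter_id", "marker_id",
                                         "direction")])),
      auto_unbox = TRUE)), "")
  tg <- store@tags
  tlines <- vapply(seq_len(nrow(tg)), function(i)
    as.character(jsonlite::toJSON(c(record = "tag", as.list(tg[i, ])),
                                  auto_unbox = TRUE)), "")
  writeLines(c(lines, vlines, tlines), path)
  invisible(path)
}

#' @rdname writeAnnotationStore
#' @export
readAnnotationStore <- function(path) {
  store <- AnnotationStore()
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  idMap <- character(0)   # file id -> store id
  deferred <- list()
  for (ln in lines) {
    obj <- jsonlite::fromJSON(ln)
    if (identical(obj$record, "marker")) {
      store <- addMarker(store, obj$author_id, obj$author_role,
                         obj$slide_id, obj$kind, obj$x_norm, obj$y_norm,
                         obj$created_zoom, title = obj$title %||% "",
                         description = obj$description %||% "",
                         image_sequence = obj$image_sequence,
                         at = obj$created_at)
      idMap[[obj$marker_id]] <- lastMarkerId(store)
    } else {
      deferred[[length(deferred) + 1L]] <- obj
    }
  }
  for (obj in deferred) {
    if (identical(obj$record, "vote")) {
      store <- castVote(store, obj$voter_id, idMap[[obj$marker_id]],
                        obj$direction)
    } else if (identical(obj$record, "tag")) {
      store <- addTag(store, obj$user_id, obj$slide_id, obj$text)
    }
  }
  store
}

`%||%` <- function(a, b) if (is.null(a)) b else a
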