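SLIDE_METADATA_FIELDS <- c("organism", "tissue_organ", "stain",
                           "developmental_stage", "preparation",
                           "section_type", "scan_level", "diagnosis")

SLIDE_ROLES <- c("public", "student", "faculty", "exam")

#' SlideStore: the slide catalogue
#'
#' Holds slide records with the eight descriptive metadata categories a
#' histology course curates (source organism, tissue/organ type, stain,
#' developmental stage, preparation, section type, scan level, diagnosis),
#' an access tier separating teaching slides from restricted exam slides,
#' and symmetric "similar slide" links. All updates are functional: every
#' mutator returns the updated store.
#'
#' @slot slides \code{data.frame} with \code{slide_id}, \code{title},
#'   \code{tileset_ref}, the eight metadata columns and \code{access_tier}
#'   (\code{"teaching"} or \code{"exam"}).
#' @slot similar \code{data.frame(a, b)} of undirected similar-slide links,
#'   stored with \code{a < b}.
#' @seealso [addSlide()], [searchSlides()], [linkSimilar()]
#' @export
setClass("SlideStore",
  representation(slides = "data.frame", similar = "data.frame"))

setValidity("SlideStore", function(object) {
  sl <- object@slides
  need <- c("slide_id", "title", "tileset_ref", SLIDE_METADATA_FIELDS,
            "access_tier")
  if (!all(need %in% names(sl))) return("slides table is missing columns")
  if (anyDuplicated(sl$slide_id)) return("duplicate slide ids")
  if (nrow(sl) && !all(sl$access_tier %in% c("teaching", "exam")))
    return("access_tier must be 'teaching' or 'exam'")
  sim <- object@similar
  if (nrow(sim)) {
    if (any(sim$a == sim$b)) return("a slide cannot be similar to itself")
    if (!all(c(sim$a, sim$b) %in% sl$slide_id))
      return("similar links reference unknown slides")
  }
  TRUE
})

#' Create an empty slide store
#'
#' @return a [SlideStore-class] with no slides.
#' @examples
#' st <- SlideStore()
#' st <- addSlide(st, "s1", "Kidney, radial section",
#'                tissue_organ = "kidney", stain = "H&E")
#' searchSlides(st, tissue_organ = "kidney")$slide_id
#' @export
SlideStore <- function() {
  cols <- c("slide_id", "title", "tileset_ref", SLIDE_METADATA_FIELDS,
            "access_tier")
  slides <- as.data.frame(setNames(rep(list(character(0)), length(cols)),
                                   cols))
  new("SlideStore", slides = slides,
      similar = data.frame(a = character(0), b = character(0)))
}

setMethod("show", "SlideStore", function(object) {
  n <- nrow(object@slides)
  cat(sprintf("SlideStore: %d slides (%d teaching, %d exam), %d similar links\n",
              n, sum(object@slides$access_tier == "teaching"),
              sum(object@slides$access_tier == "exam"),
              nrow(object@similar)))
  invisible(NULL)
})

#' Add a slide record
#'
#' @param store a [SlideStore-class].
#' @param slide_id unique opaque id.
#' @param title slide title (non-empty).
#' @param tileset_ref path or URL of the slide's tile set.
#' @param access_tier \code{"teaching"} (publicly viewable) or \code{"exam"}
#'   (visible only in exam mode).
#' @param ... metadata fields by name: \code{organism}, \code{tissue_organ},
#'   \code{stain}, \code{developmental_stage}, \code{preparation},
#'   \code{section_type}, \code{scan_level}, \code{diagnosis}.
#' @return the updated store.
#' @export
addSlide <- function(store, slide_id, title, tileset_ref = "",
                     access_tier = c("teaching", "exam"), ...) {
  stopifnot(is(store, "SlideStore"))
  access_tier <- match.arg(access_tier)
  if (!is.character(slide_id) || length(slide_id) != 1L || !nzchar(slide_id))
    stopInvalid("slide_id must be a non-empty string")
  if (!is.character(title) || length(title) != 1L || !nzchar(trimws(title)))
    stopInvalid("title must be non-empty")
  if (slide_id %in% store@slides$slide_id)
    stop("slide ", sQuote(slide_id), " already exists", call. = FALSE)
  meta <- list(...)
  bad <- setdiff(names(meta), SLIDE_METADATA_FIELDS)
  if (length(bad))
    stopInvalid("unknown metadata field(s): ", paste(bad, collapse = ", "))
  row <- as.list(setNames(rep("", length(SLIDE_METADATA_FIELDS)),
                          SLIDE_METADATA_FIELDS))
  row[names(meta)] <- vapply(meta, as.character, "")
  rec <- data.frame(slide_id = slide_id, title = title,
                    tileset_ref = tileset_ref, row,
                    access_tier = access_tier)
  store@slides <- rbind(store@slides, rec)
  validObject(store)
  store
}

#' Edit a slide's descriptive metadata (faculty only)
#'
#' Only the supplied fields change; everything stored becomes searchable.
#'
#' @inheritParams addSlide
#' @param role caller role; must be \code{"faculty"}.
#' @param title optionally replace the title.
#' @return the updated store.
#' @export
setMetadata <- function(store, slide_id, role, title = NULL, ...) {
  stopifnot(is(store, "SlideStore"))
  if (!identical(role, "faculty"))
    stop("permission denied: only faculty can edit slide metadata",
         call. = FALSE)
  i <- match(slide_id, store@slides$slide_id)
  if (is.na(i)) stop("unknown slide ", sQuote(slide_id), call. = FALSE)
  meta <- list(...)
  bad <- setdiff(names(meta), SLIDE_METADATA_FIELDS)
  if (length(bad))
    stopInvalid("unknown metadata field(s): ", paste(bad, collapse = ", "))
  for (f in names(meta)) store@slides[[f]][i] <- as.character(meta[[f]])
  if (!is.null(title)) {
    if (!nzchar(trimws(title))) stopInvalid("title must be non-empty")
    store@slides$title[i] <- title
  }
  store
}

#' Link two slides as similar examples of the same tissue
#'
#' Links are symmetric and idempotent: after \code{linkSimilar(store, a, b)}
#' each slide lists the other, and relinking the same pair is a no-op.
#'
#' @inheritParams addSlide
#' @param a,b distinct slide ids, both present in the store.
#' @return the updated store.
#' @export
linkSimilar <- function(store, a, b) {
  stopifnot(is(store, "SlideStore"))
  if (identical(a, b))
    stopInvalid("a slide cannot be linked as similar to itself")
  if (!all(c(a, b) %in% store@slides$slide_id))
    stop("both slides must exist before linking", call. = FALSE)
  lo <- min(a, b); hi <- max(a, b)
  if (!any(store@similar$a == lo & store@similar$b == hi))
    store@similar <- rbind(store@similar, data.frame(a = lo, b = hi))
  store
}

#' @rdname linkSimilar
#' @return \code{similarSlides} returns the ids linked to \code{slide_id}.
#' @export
similarSlides <- function(store, slide_id) {
  stopifnot(is(store, "SlideStore"))
  sim <- store@similar
  sort(unique(c(sim$b[sim$a == slide_id], sim$a[sim$b == slide_id])))
}

#' @rdname addSlide
#' @return \code{getSlide} returns the one-row record for \code{slide_id},
#'   with a \code{similar} attribute listing linked slides.
#' @export
getSlide <- function(store, slide_id) {
  stopifnot(is(store, "SlideStore"))
  i <- match(slide_id, store@slides$slide_id)
  if (is.na(i)) stop("unknown slide ", sQuote(slide_id), call. = FALSE)
  rec <- store@slides[i, , drop = FALSE]
  rownames(rec) <- NULL
  attr(rec, "similar") <- similarSlides(store, slide_id)
  rec
}

#' Search the slide catalogue
#'
#' Field filters are case-insensitive substring matches against the named
#' column; \code{text} matches against the title and every metadata field.
#' Slides with \code{access_tier = "exam"} are returned only to the
#' \code{"exam"} role -- under any other role they never appear, before or
#' after an exam. Results are ordered by title, then id, so output is
#' deterministic.
#'
#' @inheritParams addSlide
#' @param role one of \code{"public"}, \code{"student"}, \code{"faculty"},
#'   \code{"exam"}.
#' @param text optional free-text query.
#' @param ... field filters, e.g. \code{tissue_organ = "kidney"}.
#' @return a \code{data.frame} of matching slide records (possibly empty).
#' @export
searchSlides <- function(store, role = "public", text = NULL, ...) {
  stopifnot(is(store, "SlideStore"))
  role <- match.arg(role, SLIDE_ROLES)
  sl <- store@slides
  if (role != "exam") sl <- sl[sl$access_tier != "exam", , drop = FALSE]
  filters <- list(...)
  searchable <- c("title", SLIDE_METADATA_FIELDS)
  bad <- setdiff(names(filters), searchable)
  if (length(bad))
    stopInvalid("unknown search field(s): ", paste(bad, collapse = ", "))
  keep <- rep(TRUE, nrow(sl))
  for (f in names(filters))
    keep <- keep & grepl(tolower(filters[[f]]), tolower(sl[[f]]),
                         fixed = TRUE)
  if (!is.null(text) && nzchar(text)) {
    hay <- tolower(do.call(paste, sl[searchable]))
    keep <- keep & grepl(tolower(text), hay, fixed = TRUE)
  }
  out <- sl[keep, , drop = FALSE]
  out <- out[order(out$title, out$slide_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read and write slide stores as JSON lines
#'
#' One JSON object per line for the slide table, plus a trailing object
#' holding the similar-link table, so stores diff cleanly in version control.
#'
#' @param store a [SlideStore-class].
#' @param path file to write / read.
#' @return \code{writeSlideStore} returns \code{path} invisibly;
#'   \code{readSlideStore} returns the store.
#' @export
writeSlideStore <- function(store, path) {
  stopifnot(is(store, "SlideStore"))
  lines <- vapply(seq_len(nrow(store@slides)), function(i)
    jsonlite::toJSON(c(record = "slide",
                       as.list(store@slides[i, ])), auto_unbox = TRUE),
    "")
  sim <- vapply(seq_len(nrow(store@similar)), function(i)
    jsonlite::toJSON(c(record = "similar",
                       as.list(store@similar[i, ])), auto_unbox = TRUE),
    "")
  writeLines(c(lines, sim), path)
  invisible(path)
}

#' @rdname writeSlideStore
#' @export
readSlideStore <- function(path) {
  store <- SlideStore()
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sims <- list()
  for (ln in lines) {
    obj <- jsonlite::fromJSON(ln)
    if (identical(obj$record, "slide")) {
      args <- obj[c("slide_id", "title", "tileset_ref", "access_tier",
                    SLIDE_METADATA_FIELDS)]
      store <- do.call(addSlide, c(list(store), args))
    } else if (identical(obj$record, "similar")) {
      sims[[length(sims) + 1L]] <- obj
    }
  }
  for (s in sims) store <- linkSimilar(store, s$a, s$b)
  store
}
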