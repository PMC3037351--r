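#' Exam: a practical examination built from restricted slide pools
#'
#' Each question names a tissue and carries a pool of approved exam-tier
#' slides showing that tissue. At assignment time every student draws one
#' slide per question, so different students see different examples of the
#' same tissues. Faculty must peer-review slide image quality before an exam
#' can be assigned, modelled by the \code{approved} flag.
#'
#' @slot examId opaque exam id.
#' @slot questions \code{data.frame} with \code{question_id},
#'   \code{tissue_label}, \code{points} and a \code{pool} list-column of
#'   slide ids.
#' @slot approved logical; assignment requires \code{TRUE}.
#' @slot creditQuantum smallest partial-credit step a single grading click
#'   can award (default 0.5, i.e. credits in \{0, 0.5, 1\}).
#' @seealso [newExam()], [assignPapers()], [gradeResponse()],
#'   [exportGrades()]
#' @export
setClass("Exam",
  representation(examId = "character", questions = "data.frame",
                 approved = "logical", creditQuantum = "numeric"))

setValidity("Exam", function(object) {
  q <- object@questions
  if (!all(c("question_id", "tissue_label", "points", "pool") %in% names(q)))
    return("questions need question_id, tissue_label, points and pool")
  if (anyDuplicated(q$question_id)) return("duplicate question ids")
  if (nrow(q) && any(lengths(q$pool) < 1L))
    return("every question pool must be non-empty")
  if (nrow(q) && any(q$points <= 0)) return("points must be positive")
  qu <- object@creditQuantum
  if (length(qu) != 1L || qu <= 0 || qu > 1)
    return("creditQuantum must be in (0, 1]")
  TRUE
})

#' ExamPaper: one student's randomized exam form
#'
#' @slot examId,studentId identifiers.
#' @slot assignment \code{data.frame(question_id, slide_id)}: exactly one
#'   slide per question, drawn from that question's pool.
#' @slot responses \code{data.frame(question_id, answer_text)}.
#' @slot credits \code{data.frame(question_id, credit)} with credit
#'   fractions in [0, 1]; only answered questions carry credit.
#' @slot graderNote free text.
#' @export
setClass("ExamPaper",
  representation(examId = "character", studentId = "character",
                 assignment = "data.frame", responses = "data.frame",
                 credits = "data.frame", graderNote = "character"))

#' Create an exam
#'
#' @param examId opaque id.
#' @param questions \code{data.frame(question_id, tissue_label, points)}
#'   with a \code{pool} list-column of exam-tier slide ids.
#' @param slideStore optional [SlideStore-class]; when given, every pooled
#'   slide must exist there with \code{access_tier = "exam"}.
#' @param approved start approved (default \code{FALSE}; see
#'   [approveExam()]).
#' @param creditQuantum partial-credit step (default 0.5).
#' @return an [Exam-class].
#' @export
newExam <- function(examId, questions, slideStore = NULL, approved = FALSE,
                    creditQuantum = 0.5) {
  if (!is.null(slideStore)) {
    stopifnot(is(slideStore, "SlideStore"))
    pooled <- unique(unlist(questions$pool))
    sl <- slideStore@slides
    missing <- setdiff(pooled, sl$slide_id)
    if (length(missing))
      stopInvalid("pooled slides not in the store: ",
                  paste(missing, collapse = ", "))
    notExam <- pooled[sl$access_tier[match(pooled, sl$slide_id)] != "exam"]
    if (length(notExam))
      stopInvalid("pooled slides are not exam-tier: ",
                  paste(notExam, collapse = ", "))
  }
  new("Exam", examId = examId, questions = as.data.frame(questions),
      approved = approved, creditQuantum = creditQuantum)
}

#' @rdname newExam
#' @param exam an [Exam-class].
#' @return \code{approveExam} returns the exam with peer review recorded.
#' @export
approveExam <- function(exam) {
  stopifnot(is(exam, "Exam"))
  exam@approved <- TRUE
  exam
}

setMethod("show", "Exam", function(object) {
  cat(sprintf("Exam %s: %d questions, %s, credit step %g\n",
              object@examId, nrow(object@questions),
              if (object@approved) "approved" else "NOT approved",
              object@creditQuantum))
  invisible(NULL)
})

setMethod("show", "ExamPaper", function(object) {
  cat(sprintf("ExamPaper %s / student %s: %d questions, %d answered, %d graded\n",
              object@examId, object@studentId, nrow(object@assignment),
              nrow(object@responses), nrow(object@credits)))
  invisible(NULL)
})

#' Assign randomized exam papers
#'
#' Every student receives one slide per question, sampled uniformly (with
#' replacement across students) from that question's pool using a seeded
#' generator: the assignment is a pure function of (exam, students, seed),
#' so the same call reproduces the same forms bit for bit. The caller's RNG
#' state is left untouched.
#'
#' @param exam an approved [Exam-class].
#' @param students character vector of student ids.
#' @param seed integer seed.
#' @return named list of [ExamPaper-class], one per student.
#' @examples
#' ex <- newExam("mid", data.frame(question_id = "q1", tissue_label = "kidney",
#'                                 points = 1, pool = I(list(c("e1","e2","e3")))))
#' papers <- assignPapers(approveExam(ex), c("stu1", "stu2"), seed = 42)
#' papers$stu1@assignment
#' @export
assignPapers <- function(exam, students, seed) {
  stopifnot(is(exam, "Exam"))
  if (!exam@approved)
    stop("exam is not approved: faculty must peer review slide quality first",
         call. = FALSE)
  if (!length(students)) stopInvalid("no students to assign")
  if (any(lengths(exam@questions$pool) < 1L))
    stopInvalid("every question pool must be non-empty")
  q <- exam@questions
  withSeed(seed, {
    papers <- lapply(students, function(s) {
      picked <- vapply(q$pool,
                       function(p) p[sample.int(length(p), 1L)], "")
      new("ExamPaper", examId = exam@examId, studentId = s,
          assignment = data.frame(question_id = q$question_id,
                                  slide_id = picked),
          responses = data.frame(question_id = character(0),
                                 answer_text = character(0)),
          credits = data.frame(question_id = character(0),
                               credit = numeric(0)),
          graderNote = "")
    })
    names(papers) <- students
    papers
  })
}

#' Record a student's typed answer
#'
#' @param paper an [ExamPaper-class].
#' @param question_id question being answered.
#' @param answer_text the student's free-text identification.
#' @return the updated paper (papers stay editable until grading).
#' @export
submitResponse <- function(paper, question_id, answer_text) {
  stopifnot(is(paper, "ExamPaper"))
  if (!(question_id %in% paper@assignment$question_id))
    stop("question ", sQuote(question_id), " is not on this paper",
         call. = FALSE)
  rs <- paper@responses
  rs <- rs[rs$question_id != question_id, , drop = FALSE]
  paper@responses <- rbind(rs, data.frame(question_id = question_id,
                                          answer_text = answer_text))
  paper
}

#' Grade one response with full or partial credit
#'
#' One grading action per question: the credit fraction must be a multiple
#' of the exam's credit quantum (default steps 0, 0.5, 1) and within [0, 1].
#' Regrading replaces the prior credit. Only answered questions can be
#' graded -- the grading view pairs the correct answer with the typed
#' student response.
#'
#' @inheritParams submitResponse
#' @param exam the [Exam-class] the paper belongs to (supplies the credit
#'   quantum).
#' @param credit fraction in [0, 1].
#' @return the updated paper.
#' @export
gradeResponse <- function(paper, exam, question_id, credit) {
  stopifnot(is(paper, "ExamPaper"), is(exam, "Exam"))
  if (!(question_id %in% paper@responses$question_id))
    stop("question ", sQuote(question_id),
         " has no response to grade", call. = FALSE)
  if (!is.numeric(credit) || length(credit) != 1L || is.na(credit) ||
      credit < 0 || credit > 1)
    stopInvalid("credit must be a fraction in [0,1]")
  steps <- credit / exam@creditQuantum
  if (abs(steps - round(steps)) > 1e-9)
    stopInvalid("credit must be a multiple of the credit quantum (",
                exam@creditQuantum, ")")
  cr <- paper@credits
  cr <- cr[cr$question_id != question_id, , drop = FALSE]
  paper@credits <- rbind(cr, data.frame(question_id = question_id,
                                        credit = credit))
  paper
}

#' @rdname gradeResponse
#' @return \code{paperScore} returns \code{list(points, total, percent)}:
#'   earned points (sum of credit x points), total available points, and
#'   the percentage score.
#' @export
paperScore <- function(paper, exam) {
  stopifnot(is(paper, "ExamPaper"), is(exam, "Exam"))
  q <- exam@questions
  pts <- q$points[match(paper@credits$question_id, q$question_id)]
  earned <- sum(paper@credits$credit * pts)
  total <- sum(q$points)
  list(points = earned, total = total, percent = 100 * earned / total)
}

#' Export a performance report
#'
#' One row per student with per-question credits, total points and percent
#' score, in stable column order, written as plain CSV so it round-trips
#' through any standard parser and imports into a learning management
#' system.
#'
#' @param exam the [Exam-class].
#' @param papers list of fully graded [ExamPaper-class] objects.
#' @param file optional path; when given the table is written with
#'   [utils::write.csv()].
#' @return the report \code{data.frame} (invisibly if \code{file} is given).
#' @export
exportGrades <- function(exam, papers, file = NULL) {
  stopifnot(is(exam, "Exam"))
  q <- exam@questions
  ungraded <- Filter(function(p)
    !all(q$question_id %in% p@credits$question_id), papers)
  if (length(ungraded))
    stop("ungraded papers: ",
         paste(vapply(ungraded, function(p) p@studentId, ""),
               collapse = ", "), call. = FALSE)
  rows <- lapply(papers, function(p) {
    cr <- p@credits$credit[match(q$question_id, p@credits$question_id)]
    sc <- paperScore(p, exam)
    out <- data.frame(student_id = p@studentId)
    for (i in seq_len(nrow(q)))
      out[[paste0("credit_", q$question_id[i])]] <- cr[i]
    out$total <- sc$points
    out$percent <- sc$percent
    out
  })
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  if (!is.null(file)) {
    utils::write.csv(report, file, row.names = FALSE)
    return(invisible(report))
  }
  report
}

#' Read and write exams and papers as JSON
#'
#' @param exam an [Exam-class]; \code{papers} an optional list of
#'   [ExamPaper-class].
#' @param path JSON file.
#' @return \code{readExam} returns \code{list(exam, papers)}.
#' @export
writeExam <- function(exam, path, papers = list()) {
  stopifnot(is(exam, "Exam"))
  obj <- list(
    exam_id = exam@examId, approved = exam@approved,
    credit_quantum = exam@creditQuantum,
    questions = lapply(seq_len(nrow(exam@questions)), function(i) list(
      question_id = exam@questions$question_id[i],
      tissue_label = exam@questions$tissue_label[i],
      points = exam@questions$points[i],
      pool = exam@questions$pool[[i]])),
    papers = lapply(papers, function(p) list(
      student_id = p@studentId, assignment = p@assignment,
      responses = p@responses, credits = p@credits,
      grader_note = p@graderNote)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeExam
#' @export
readExam <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  qs <- obj$questions
  questions <- data.frame(
    question_id = vapply(qs, function(x) x$question_id, ""),
    tissue_label = vapply(qs, function(x) x$tissue_label, ""),
    points = vapply(qs, function(x) as.numeric(x$points), 0))
  questions$pool <- lapply(qs, function(x) unlist(x$pool))
  exam <- newExam(obj$exam_id, questions, approved = isTRUE(obj$approved),
                  creditQuantum = obj$credit_quantum)
  bindRows <- function(x, template) {
    if (!length(x)) return(template)
    do.call(rbind, lapply(x, function(r) as.data.frame(r)))
  }
  papers <- lapply(obj$papers, function(p) {
    emptyRe <- data.frame(question_id = character(0),
                          answer_text = character(0))
    emptyCr <- data.frame(question_id = character(0), credit = numeric(0))
    new("ExamPaper", examId = obj$exam_id, studentId = p$student_id,
        assignment = bindRows(p$assignment,
                              data.frame(question_id = character(0),
                                         slide_id = character(0))),
        responses = bindRows(p$responses, emptyRe),
        credits = bindRows(p$credits, emptyCr),
        graderNote = p$grader_note %||% "")
  })
  names(papers) <- vapply(papers, function(p) p@studentId, "")
  list(exam = exam, papers = papers)
}
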