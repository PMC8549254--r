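# Contour-exchange JSON, cohort CSV, and the run report.
#
# No standard text format exists for CMR contour stacks, so the package
# defines a versioned JSON schema mirroring the in-memory types: lengths in
# mm, contour vertex arrays ordered, `schema_version` required.  CSV dialect
# everywhere: comma separated, UTF-8, "." decimal, mandatory header row.

CONTOUR_SCHEMA_VERSION <- "1.0"

#' Write a contour stack to JSON
#'
#' @param stack a [contour_stack].
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_contour_stack <- function(stack, path) {
  ct_out <- function(ct) if (is.null(ct)) NULL else unname(apply(ct$vertices, 1, as.numeric, simplify = FALSE))
  pt <- function(p) if (is.null(p)) NULL else as.numeric(p)
  drop_null <- function(l) l[!vapply(l, is.null, logical(1))]
  slices <- lapply(stack$slices, function(s) {
    drop_null(list(
      index = s$index, origin = as.numeric(s$origin), normal = as.numeric(s$normal),
      contours = drop_null(list(
        ED = drop_null(list(epicardial = ct_out(s$epicardial$ED),
                            endocardial = ct_out(s$endocardial$ED))),
        ES = drop_null(list(epicardial = ct_out(s$epicardial$ES),
                            endocardial = ct_out(s$endocardial$ES))))),
      insertion_points = drop_null(list(
        ED = if (is.null(s$insertions$ED)) NULL else
          list(anterior = pt(s$insertions$ED$anterior),
               inferior = pt(s$insertions$ED$inferior)),
        ES = if (is.null(s$insertions$ES)) NULL else
          list(anterior = pt(s$insertions$ES$anterior),
               inferior = pt(s$insertions$ES$inferior)))),
      septal_hint = pt(s$septal_hint)))
  })
  lm <- stack$landmarks
  obj <- drop_null(list(
    schema_version = CONTOUR_SCHEMA_VERSION,
    subject_id = stack$subject_id,
    slice_thickness_mm = stack$slice_thickness_mm,
    slice_gap_mm = stack$slice_gap_mm,
    heart_rate_bpm = stack$heart_rate_bpm,
    landmarks = if (is.null(lm)) NULL else
      list(ED = lapply(lm$ED, as.numeric), ES = lapply(lm$ES, as.numeric),
           apex = as.numeric(lm$apex)),
    slices = slices))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a contour stack from JSON
#'
#' Validates the schema (errors name the JSON path of the offending field),
#' normalizes contour orientation to counterclockwise-from-apex (noting any
#' flipped contour), and warns about slices that carry epicardial contours
#' at both phases but lack insertion points (those slices are excluded from
#' the radial computation).
#'
#' @param path JSON file path.
#' @return A [contour_stack].
#' @export
read_contour_stack <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                            simplifyMatrix = TRUE)
  need <- function(x, where) {
    if (is.null(x)) stop(sprintf("contour JSON: missing required field '%s'", where))
    x
  }
  sv <- need(obj$schema_version, "schema_version")
  if (!identical(sv, CONTOUR_SCHEMA_VERSION))
    stop(sprintf("unknown schema_version '%s' (expected '%s')", sv, CONTOUR_SCHEMA_VERSION))
  need(obj$subject_id, "subject_id")
  need(obj$slice_thickness_mm, "slice_thickness_mm")
  mk_contour <- function(v, surface, phase, where) {
    if (is.null(v)) return(NULL)
    m <- if (is.matrix(v)) v else do.call(rbind, v)
    if (!is.numeric(m) || ncol(m) != 3L)
      stop(sprintf("contour JSON: %s must be an array of [x,y,z] points", where))
    planar_contour(m, surface, phase, validate = TRUE)
  }
  pt_in <- function(p, where) {
    if (is.null(p)) return(NULL)
    p <- as.numeric(p)
    if (length(p) != 3L || !all(is.finite(p)))
      stop(sprintf("contour JSON: %s must be a finite [x,y,z] point", where))
    p
  }
  slices <- lapply(seq_along(obj$slices), function(i) {
    s <- obj$slices[[i]]
    at <- function(f) sprintf("slices[%d].%s", i - 1L, f)
    epicardial <- list(); endocardial <- list(); insertions <- list()
    for (ph in c("ED", "ES")) {
      cts <- s$contours[[ph]]
      epicardial[[ph]] <- mk_contour(cts$epicardial, "epicardial", ph,
                                     at(sprintf("contours.%s.epicardial", ph)))
      endocardial[[ph]] <- mk_contour(cts$endocardial, "endocardial", ph,
                                      at(sprintf("contours.%s.endocardial", ph)))
      ip <- s$insertion_points[[ph]]
      if (!is.null(ip)) {
        ant <- pt_in(ip$anterior, at(sprintf("insertion_points.%s.anterior", ph)))
        inf <- pt_in(ip$inferior, at(sprintf("insertion_points.%s.inferior", ph)))
        if (!is.null(ant) && !is.null(inf))
          insertions[[ph]] <- list(anterior = ant, inferior = inf)
      }
    }
    lv_slice(index = need(s$index, at("index")),
             origin = pt_in(need(s$origin, at("origin")), at("origin")),
             normal = pt_in(need(s$normal, at("normal")), at("normal")),
             epicardial = epicardial[!vapply(epicardial, is.null, logical(1))],
             endocardial = endocardial[!vapply(endocardial, is.null, logical(1))],
             insertions = insertions,
             septal_hint = pt_in(s$septal_hint, at("septal_hint")))
  })
  lm <- NULL
  if (!is.null(obj$landmarks)) {
    lm <- landmark_set(obj$landmarks$ED, obj$landmarks$ES,
                       pt_in(need(obj$landmarks$apex, "landmarks.apex"), "landmarks.apex"))
  }
  stack <- contour_stack(subject_id = obj$subject_id, slices = slices,
                         slice_thickness_mm = obj$slice_thickness_mm,
                         slice_gap_mm = if (is.null(obj$slice_gap_mm)) 0 else obj$slice_gap_mm,
                         landmarks = lm,
                         heart_rate_bpm = obj$heart_rate_bpm)
  fl <- attr(stack, "flipped")
  if (!is.null(fl) && fl > 0)
    message(sprintf("read_contour_stack: normalized %d clockwise contour(s) to counterclockwise", fl))
  incomplete <- vapply(stack$slices, function(s) {
    both_epi <- !is.null(s$epicardial$ED) && !is.null(s$epicardial$ES)
    both_ins <- !is.null(s$insertions$ED) && !is.null(s$insertions$ES)
    both_epi && !both_ins
  }, logical(1))
  if (any(incomplete))
    warning(sprintf("slice(s) %s lack insertion points at one or both phases; excluded from the radial computation",
                    paste(which(incomplete) - 1L, collapse = ", ")))
  stack
}

#' Write a cohort table to CSV
#'
#' @param cohort a `cohort_table`.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8", na = "")
  invisible(path)
}

#' Read a cohort table from CSV
#'
#' @param path CSV path with the cohort schema (see [generate_cohort]).
#' @return A `cohort_table`.
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                        na.strings = c("", "NA"))
  missing <- setdiff(cohort_columns, names(df))
  if (length(missing))
    stop(sprintf("cohort CSV is missing column(s): %s", paste(missing, collapse = ", ")))
  for (nm in c("lbbb", "ischemic", "dyssync", "lge")) df[[nm]] <- as.logical(df[[nm]])
  if (anyDuplicated(df$id)) stop("cohort ids must be unique")
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Assemble a run report
#'
#' @param subjects list of [sv_decompose] results (may be empty).
#' @param tables named list of data frames (cohort statistics tables).
#' @param seed the seed used for the run.
#' @param config optional configuration list (hashed into the provenance
#'   block).
#' @return An object of class `run_report`.
#' @export
run_report <- function(subjects = list(), tables = list(), seed = NA_integer_,
                       config = NULL) {
  rows <- if (length(subjects)) do.call(rbind, lapply(subjects, summary)) else NULL
  structure(list(subjects = rows, tables = tables,
                 provenance = list(
                   package = "svdecomp",
                   version = as.character(utils::packageVersion("svdecomp")),
                   seed = seed,
                   config_hash = if (is.null(config)) NA_character_ else
                     format(sum(utf8ToInt(paste(deparse(config), collapse = ""))),
                            scientific = FALSE),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))),
            class = "run_report")
}

#' Write a run report
#'
#' Writes `results.csv` (one row per subject, display columns rounded to 2
#' decimals), one `table_<name>.csv` per statistics table, and
#' `report.json` at full numeric precision.
#'
#' @param report a [run_report].
#' @param dir output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (file.access(dir, 2) != 0) stop(sprintf("output directory '%s' is not writable", dir))
  files <- character(0)
  res_path <- file.path(dir, "results.csv")
  subj <- report$subjects
  if (is.null(subj)) {
    subj <- data.frame(subject_id = character(0), edv_ml = numeric(0),
                       esv_ml = numeric(0), sv_ml = numeric(0))
  } else {
    num <- vapply(subj, is.numeric, logical(1))
    subj[num] <- lapply(subj[num], round, 2)
  }
  utils::write.csv(subj, res_path, row.names = FALSE, quote = FALSE, na = "")
  files <- c(files, res_path)
  for (nm in names(report$tables)) {
    p <- file.path(dir, sprintf("table_%s.csv", nm))
    utils::write.csv(report$tables[[nm]], p, row.names = FALSE, quote = FALSE, na = "")
    files <- c(files, p)
  }
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(list(subjects = report$subjects, tables = report$tables,
                            provenance = report$provenance),
                       json_path, auto_unbox = TRUE, digits = NA, na = "null")
  files <- c(files, json_path)
  invisible(files)
}
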