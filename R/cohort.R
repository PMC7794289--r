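#' Match demographically identical control groups
#'
#' For each AD image, draws `n_groups` distinct normal-control (NC) images
#' with the identical (age, sex, eye) combination, without replacement across
#' the whole assignment, and assigns one to each of `n_groups` redundant
#' control groups. Every control group's (age, sex, eye) multiset therefore
#' equals the AD group's exactly, and no NC image is reused. Matching is
#' exact integer-year age equality; insufficient candidates is an error that
#' names the deficient AD rows, never a relaxed match.
#'
#' @param table subject table (data.frame with columns subject_id, age, sex,
#'   eye, diagnosis, image_id).
#' @param n_groups number of redundant control groups (0 gives an empty
#'   assignment).
#' @param seed integer RNG seed; ties among eligible candidates are broken by
#'   a seeded random draw.
#' @param same_subject_blocks if `TRUE`, all images of one AD subject draw
#'   their group-g controls from a single NC subject (requires candidate NC
#'   subjects whose unused images cover the AD subject's eye multiset).
#' @return an object of class `control_assignment`: data.frame `assignment`
#'   with columns (ad_image_id, group, nc_image_id), plus `n_groups`.
#' @export
match_controls <- function(table, n_groups, seed = 1L,
                           same_subject_blocks = FALSE) {
  cols <- c("subject_id", "age", "sex", "eye", "diagnosis", "image_id")
  if (!is.data.frame(table) || !all(cols %in% names(table)))
    stop("malformed subject table: need columns ",
         paste(cols, collapse = ", "))
  stopifnot(n_groups >= 0)
  empty <- data.frame(ad_image_id = character(), group = integer(),
                      nc_image_id = character())
  if (n_groups == 0)
    return(structure(list(assignment = empty, n_groups = 0L),
                     class = "control_assignment"))
  ad <- table[table$diagnosis == "AD", , drop = FALSE]
  nc <- table[table$diagnosis == "NC", , drop = FALSE]
  key <- function(d) paste(d$age, d$sex, d$eye, sep = "|")
  ad$key <- key(ad); nc$key <- key(nc)
  # precondition: every AD row has enough exact-match candidates in the pool
  cand_n <- vapply(ad$key, function(k) sum(nc$key == k), integer(1))
  short <- cand_n < n_groups
  if (any(short))
    stop("insufficient matched NC candidates for AD rows: ",
         paste(ad$image_id[short], collapse = ", "))
  with_seed(seed, {
    used <- rep(FALSE, nrow(nc))
    out <- vector("list", nrow(ad))
    if (same_subject_blocks) {
      for (sid in unique(ad$subject_id)) {
        rows <- ad[ad$subject_id == sid, , drop = FALSE]
        for (g in seq_len(n_groups)) {
          ok <- vapply(unique(nc$subject_id), function(ns) {
            pool <- nc[nc$subject_id == ns & !used, , drop = FALSE]
            all(rows$key %in% pool$key) &&
              all(table(factor(rows$key, unique(rows$key))) <=
                    table(factor(pool$key, unique(rows$key))))
          }, logical(1))
          cands <- unique(nc$subject_id)[ok]
          if (length(cands) == 0)
            stop("insufficient same-subject-block candidates for AD subject ",
                 sid, " in group ", g)
          pick <- sample(cands, 1)
          for (i in seq_len(nrow(rows))) {
            j <- which(nc$subject_id == pick & !used & nc$key == rows$key[i])[1]
            used[j] <- TRUE
            out[[length(out) + 1]] <- data.frame(
              ad_image_id = rows$image_id[i], group = g,
              nc_image_id = nc$image_id[j])
          }
        }
      }
      out <- out[!vapply(out, is.null, logical(1))]
    } else {
      for (i in seq_len(nrow(ad))) {
        cand <- which(nc$key == ad$key[i] & !used)
        if (length(cand) < n_groups)
          stop("matched NC candidates exhausted for AD row ", ad$image_id[i],
               "; a different draw order may help")
        pick <- cand[sample.int(length(cand), n_groups)]
        used[pick] <- TRUE
        out[[i]] <- data.frame(ad_image_id = ad$image_id[i],
                               group = seq_len(n_groups),
                               nc_image_id = nc$image_id[pick])
      }
    }
    structure(list(assignment = do.call(rbind, out),
                   n_groups = as.integer(n_groups)),
              class = "control_assignment")
  })
}

#' Image ids in one control group
#' @param x a [match_controls()] result.
#' @param g group index in `1:n_groups`.
#' @return character vector of NC image ids, aligned with the AD image order.
#' @export
control_group_ids <- function(x, g) {
  stopifnot(inherits(x, "control_assignment"), g >= 1, g <= x$n_groups)
  x$assignment$nc_image_id[x$assignment$group == g]
}

#' @export
print.control_assignment <- function(x, ...) {
  cat("Matched control assignment:",
      length(unique(x$assignment$ad_image_id)), "AD images x",
      x$n_groups, "control groups\n")
  invisible(x)
}
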