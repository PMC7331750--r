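ZYGOSITY_LEVELS <- c("MZm", "MZf", "DZm", "DZf", "DOS")

#' Twin cohort container
#'
#' One row per twin pair, in the wide dialect used throughout the package:
#' `pair_id`, `zygosity` (one of MZm, MZf, DZm, DZf, DOS), `sex1`, `sex2`
#' (`"M"`/`"F"`), `age` (years, shared by the pair) and two columns
#' `<test>_t1`, `<test>_t2` per phenotype. `NA` marks a missing score.
#'
#' @param data A data.frame with the columns above.
#' @param phenotypes Character vector of phenotype (test) names.
#' @return An object of class `twin_cohort` (a data.frame).
#' @export
twin_cohort <- function(data, phenotypes) {
  need <- c("pair_id", "zygosity", "sex1", "sex2", "age",
            paste0(rep(phenotypes, each = 2), c("_t1", "_t2")))
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("missing cohort columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (!all(data$zygosity %in% ZYGOSITY_LEVELS))
    stop("zygosity must be one of ", paste(ZYGOSITY_LEVELS, collapse = ", "),
         call. = FALSE)
  if (!all(unlist(data[c("sex1", "sex2")]) %in% c("M", "F")))
    stop("sex1/sex2 must be 'M' or 'F'", call. = FALSE)
  structure(as.data.frame(data), phenotypes = phenotypes,
            class = c("twin_cohort", "data.frame"))
}

#' Phenotype names of a twin cohort
#' @param cohort A [twin_cohort()].
#' @return Character vector of test names.
#' @export
phenotypes <- function(cohort) attr(cohort, "phenotypes")

#' @export
print.twin_cohort <- function(x, ...) {
  cat(sprintf("Twin cohort: %d pairs, %d phenotypes (%s)\n",
              nrow(x), length(phenotypes(x)),
              paste(phenotypes(x), collapse = ", ")))
  tab <- table(factor(x$zygosity, ZYGOSITY_LEVELS))
  cat("  pairs by zygosity:", paste(names(tab), tab, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.twin_cohort <- function(object, ...) {
  ph <- phenotypes(object)
  out <- do.call(rbind, lapply(ph, function(p) {
    v <- c(object[[paste0(p, "_t1")]], object[[paste0(p, "_t2")]])
    data.frame(phenotype = p, n = sum(!is.na(v)),
               missing = mean(is.na(v)), mean = mean(v, na.rm = TRUE),
               sd = stats::sd(v, na.rm = TRUE))
  }))
  rownames(out) <- NULL
  out
}

#' Per-pair score matrix for one phenotype
#' @param cohort A [twin_cohort()].
#' @param phenotype A phenotype name.
#' @return A two-column matrix (twin 1, twin 2), one row per pair.
#' @export
pair_scores <- function(cohort, phenotype) {
  if (!phenotype %in% phenotypes(cohort))
    stop("unknown phenotype: ", phenotype, call. = FALSE)
  cbind(t1 = cohort[[paste0(phenotype, "_t1")]],
        t2 = cohort[[paste0(phenotype, "_t2")]])
}

#' Person-level (long) view of a cohort
#'
#' Stacks both members of every pair into one row per person, used by the
#' preprocessing steps that operate on individuals.
#'
#' @param cohort A [twin_cohort()].
#' @return A data.frame with `pair_id`, `member` (1 or 2), `zygosity`,
#'   `sex`, `age` and one column per phenotype.
#' @export
cohort_persons <- function(cohort) {
  ph <- phenotypes(cohort)
  one <- function(m) {
    d <- data.frame(pair_id = cohort$pair_id, member = m,
                    zygosity = cohort$zygosity,
                    sex = cohort[[paste0("sex", m)]], age = cohort$age)
    for (p in ph) d[[p]] <- cohort[[paste0(p, "_t", m)]]
    d
  }
  rbind(one(1L), one(2L))
}

#' Write / read a twin cohort as wide CSV
#'
#' The on-disk dialect is plain CSV with one row per pair and empty cells
#' for missing scores.
#'
#' @param cohort A [twin_cohort()].
#' @param path File path.
#' @return `write_twin_cohort` returns `path` invisibly; `read_twin_cohort`
#'   returns a [twin_cohort()].
#' @export
write_twin_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_twin_cohort
#' @param phenotypes Optional phenotype names; inferred from paired
#'   `_t1`/`_t2` columns when omitted.
#' @export
read_twin_cohort <- function(path, phenotypes = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(phenotypes)) {
    t1 <- sub("_t1$", "", grep("_t1$", names(d), value = TRUE))
    t2 <- sub("_t2$", "", grep("_t2$", names(d), value = TRUE))
    phenotypes <- intersect(t1, t2)
  }
  twin_cohort(d, phenotypes)
}
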