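# Category vocabularies. "Fine" T/M carry the 8th-edition subdescriptors
# (T2a vs T2b changes the N0 sub-stage); "coarse" is the granularity at
# which subgroups are clustered.
.histologies <- c("ADC", "SCC")
.t_fine <- c("T1a", "T1b", "T1c", "T2a", "T2b", "T3", "T4")
.t_coarse <- c("T1", "T2", "T3", "T4")
.n_levels <- c("N0", "N1", "N2", "N3")
.m_fine <- c("M0", "M1a", "M1b", "M1c")
.m_coarse <- c("M0", "M1")
.substages <- c("IA", "IB", "IIA", "IIB", "IIIA", "IIIB", "IIIC", "IV")
.stages <- c("I", "II", "III", "IV")
.substage_stage <- c(IA = "I", IB = "I", IIA = "II", IIB = "II",
                     IIIA = "III", IIIB = "III", IIIC = "III", IV = "IV")

#' Category level sets used by the staging tables
#'
#' Returns the controlled vocabularies for histology, T, N, M, sub-stage and
#' stage labels. Fine T/M levels carry 8th-edition subdescriptors
#' (T1a/T1b/T1c, T2a/T2b, M1a/M1b/M1c); coarse levels are the collapsed
#' categories (T1-T4, M0/M1) at which survival-curve clustering operates.
#'
#' @return Named list of character vectors: `histology`, `t_fine`,
#'   `t_coarse`, `n`, `m_fine`, `m_coarse`, `substage`, `stage`.
#' @export
tnm_levels <- function() {
  list(histology = .histologies, t_fine = .t_fine, t_coarse = .t_coarse,
       n = .n_levels, m_fine = .m_fine, m_coarse = .m_coarse,
       substage = .substages, stage = .stages)
}

.check_enum <- function(x, levels, field) {
  bad <- !(x %in% levels)
  if (any(bad)) {
    stop("invalid ", field, " value(s): ",
         paste(unique(x[bad]), collapse = ", "),
         " (allowed: ", paste(levels, collapse = ", "), ")", call. = FALSE)
  }
  invisible(TRUE)
}

#' Validate TNM category fields
#'
#' Checks that histology, T, N and M values are drawn from their controlled
#' vocabularies. T and M may be given at fine (subdescriptor) or coarse
#' granularity; the two may not be mixed within one vector.
#'
#' @param histology Character vector, `"ADC"` or `"SCC"`.
#' @param t Character vector of T categories.
#' @param n Character vector of N categories.
#' @param m Character vector of M categories.
#' @return Invisibly `TRUE`; stops with a message naming the offending field
#'   otherwise.
#' @export
validate_tnm <- function(histology, t, n, m) {
  .check_enum(histology, .histologies, "histology")
  .check_enum(t, c(.t_fine, .t_coarse), "t")
  .check_enum(n, .n_levels, "n")
  .check_enum(m, c(.m_fine, .m_coarse), "m")
  invisible(TRUE)
}

#' Collapse T and M subdescriptors to clustering granularity
#'
#' Deterministically coarsens fine TNM categories: T1a/T1b/T1c to T1,
#' T2a/T2b to T2, M1a/M1b/M1c to M1. Already-coarse values pass through
#' unchanged.
#'
#' @inheritParams validate_tnm
#' @return A data.frame with columns `histology`, `t`, `n`, `m` at coarse
#'   granularity.
#' @examples
#' coarsen_tnm("ADC", "T1c", "N2", "M0")
#' @export
coarsen_tnm <- function(histology, t, n, m) {
  validate_tnm(histology, t, n, m)
  t2 <- sub("^(T1|T2)[abc]$", "\\1", t)
  m2 <- sub("^M1[abc]$", "M1", m)
  data.frame(histology = histology, t = t2, n = n, m = m2,
             stringsAsFactors = FALSE)
}

.is_fine_t <- function(t) t %in% c("T1a", "T1b", "T1c", "T2a", "T2b")
.is_fine_m <- function(m) m %in% c("M1a", "M1b", "M1c")

#' 8th-edition AJCC/UICC sub-stage assignment
#'
#' Assigns the 8th-edition lung cancer sub-stage to a TNM category, with
#' IA1/IA2/IA3 collapsed to IA and IVA/IVB collapsed to IV (eight sub-stage
#' groups). Any M1 subdescriptor maps to stage IV. Histology does not enter
#' the 8th-edition grouping; it is accepted for interface symmetry with the
#' modified systems.
#'
#' @inheritParams validate_tnm
#' @param histology Optional; ignored by the 8th-edition rule.
#' @return Character vector of sub-stage labels (`IA` ... `IV`).
#' @examples
#' assign_substage_8th("ADC", "T1b", "N0", "M0")  # "IA"
#' assign_substage_8th("SCC", "T1a", "N1", "M0")  # "IIB"
#' @export
assign_substage_8th <- function(histology = "ADC", t, n, m) {
  validate_tnm(histology, t, n, m)
  len <- max(length(histology), length(t), length(n), length(m))
  t <- rep_len(t, len); n <- rep_len(n, len); m <- rep_len(m, len)
  ambig <- .is_ambiguous_coarse_t(t, n) & m == "M0"
  if (any(ambig)) {
    stop("coarse T category ", paste(unique(t[ambig]), collapse = ", "),
         " with N0/M0 is ambiguous under the 8th edition ",
         "(T2a maps to IB but T2b to IIA); supply fine T categories",
         call. = FALSE)
  }
  out <- character(len)
  m1 <- m != "M0"
  out[m1] <- "IV"
  tt <- sub("^(T1)[abc]$", "\\1", t)  # T1a/b/c all behave alike after IA collapse
  idx <- !m1
  out[idx] <- .substage_m0(tt[idx], t[idx], n[idx])
  out
}

# Coarse T2 with N0 cannot be staged under the 8th edition (T2a -> IB,
# T2b -> IIA); every other coarse cell is unambiguous.
.is_ambiguous_coarse_t <- function(t, n) t == "T2" & n == "N0"

.substage_m0 <- function(t1_collapsed, t_orig, n) {
  out <- character(length(n))
  for (i in seq_along(n)) {
    t <- t1_collapsed[i]
    out[i] <- switch(n[i],
      N0 = switch(t, T1 = "IA",
                  T2a = "IB", T2b = "IIA",
                  T2 = "IB",  # unreachable: guarded by ambiguity check
                  T3 = "IIB", T4 = "IIIA"),
      N1 = if (t %in% c("T1", "T2a", "T2b", "T2")) "IIB" else "IIIA",
      N2 = if (t %in% c("T1", "T2a", "T2b", "T2")) "IIIA" else "IIIB",
      N3 = if (t %in% c("T1", "T2a", "T2b", "T2")) "IIIB" else "IIIC")
  }
  out
}

#' Stage of a sub-stage label
#'
#' Maps sub-stage labels to their stage under the fixed nesting
#' \{IA,IB\} in I, \{IIA,IIB\} in II, \{IIIA,IIIB,IIIC\} in III, IV = IV.
#'
#' @param substage Character vector of sub-stage labels.
#' @return Character vector of stage labels.
#' @export
substage_to_stage <- function(substage) {
  .check_enum(substage, .substages, "substage")
  unname(.substage_stage[substage])
}

#' Ordinal rank of a stage or sub-stage label
#'
#' @param x Character vector of stage (`I`-`IV`) or sub-stage (`IA`-`IV`)
#'   labels.
#' @param level `"stage"` or `"substage"`.
#' @return Integer ranks, 1 = earliest (best prognosis).
#' @export
stage_rank <- function(x, level = c("substage", "stage")) {
  level <- match.arg(level)
  lev <- if (level == "substage") .substages else .stages
  .check_enum(x, lev, level)
  match(x, lev)
}

.new_stage_map <- function(system, granularity, entries) {
  stopifnot(all(c("histology", "t", "n", "m", "substage", "source") %in%
                names(entries)))
  entries$stage <- substage_to_stage(entries$substage)
  entries <- entries[c("histology", "t", "n", "m", "stage", "substage",
                       "source")]
  rownames(entries) <- NULL
  structure(list(system = system, granularity = granularity,
                 entries = entries),
            class = "stage_map")
}

#' @export
print.stage_map <- function(x, ...) {
  cat("Stage map '", x$system, "' (", x$granularity, " granularity, ",
      nrow(x$entries), " entries)\n", sep = "")
  cat("  sources:",
      paste(sprintf("%s=%d", names(table(x$entries$source)),
                    as.integer(table(x$entries$source))), collapse = ", "),
      "\n")
  invisible(x)
}

.fine_grid <- function() {
  expand.grid(histology = .histologies, t = .t_fine, n = .n_levels,
              m = .m_fine, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

.coarse_grid <- function() {
  expand.grid(histology = .histologies, t = .t_coarse, n = .n_levels,
              m = .m_coarse, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

#' The 8th-edition stage map
#'
#' Total lookup table over the fine TNM grid (2 histologies x 7 T x 4 N x
#' 4 M) giving the 8th-edition sub-stage of every cell; histology does not
#' alter the assignment but is carried so the map shares its key domain
#' with histology-aware maps.
#'
#' @return A `stage_map` with `system = "ajcc8"`, fine granularity, and
#'   entry source `"standard"`.
#' @export
stage_map_8th <- function() {
  g <- .fine_grid()
  g$substage <- assign_substage_8th(g$histology, g$t, g$n, g$m)
  g$source <- "standard"
  .new_stage_map("ajcc8", "fine", g)
}

# Explicit histology-specific reassignments of the modified grouping,
# stated at the granularity they require. Cells not listed keep their
# 8th-edition sub-stage (source "default"); M1 cells in particular stay at
# IV because the published shifts of selected M1 cases into IIIB/IIIC do
# not identify which M subdescriptor moves where.
.modified_moves <- function() {
  adc <- rbind(
    expand.grid(t = c("T1a", "T1b", "T1c"), n = "N1", to = "IB",
                stringsAsFactors = FALSE),
    expand.grid(t = c("T1a", "T1b", "T1c"), n = "N2", to = "IIA",
                stringsAsFactors = FALSE),
    expand.grid(t = c("T2a", "T2b"), n = "N1", to = "IIA",
                stringsAsFactors = FALSE),
    data.frame(t = "T3", n = "N0", to = "IIA"),
    data.frame(t = "T4", n = "N0", to = "IIB"),
    expand.grid(t = c("T3", "T4"), n = "N1", to = "IIB",
                stringsAsFactors = FALSE),
    expand.grid(t = c("T2a", "T2b"), n = "N2", to = "IIB",
                stringsAsFactors = FALSE),
    expand.grid(t = c("T3", "T4"), n = "N2", to = "IIIA",
                stringsAsFactors = FALSE),
    expand.grid(t = c("T2a", "T2b"), n = "N3", to = "IIIA",
                stringsAsFactors = FALSE),
    expand.grid(t = c("T3", "T4"), n = "N3", to = "IIIB",
                stringsAsFactors = FALSE))
  adc$histology <- "ADC"
  scc <- rbind(
    expand.grid(t = c("T1a", "T1b", "T1c"), n = "N0", to = "IB",
                stringsAsFactors = FALSE),
    data.frame(t = "T2a", n = "N0", to = "IIA"),
    data.frame(t = "T2b", n = "N0", to = "IIB"))
  scc$histology <- "SCC"
  out <- rbind(adc, scc)
  out$m <- "M0"
  out
}

#' The published modified stage map
#'
#' The modified grouping reassigns histology-specific M0 cells so that
#' adenocarcinoma, which carries the better prognosis at equal anatomic
#' extent, generally sits one sub-stage lower than squamous cell carcinoma
#' of the same TNM. Cells with an explicit published reassignment carry
#' source `"paper"`; all remaining cells default to their 8th-edition
#' sub-stage with source `"default"` (including every M1 cell, which stays
#' at IV because the published M1 shifts are not fully specified).
#'
#' @return A `stage_map` with `system = "paper_modified"`, fine granularity.
#' @export
stage_map_paper_modified <- function() {
  base <- stage_map_8th()$entries
  base$source <- "default"
  moves <- .modified_moves()
  key <- function(d) paste(d$histology, d$t, d$n, d$m)
  idx <- match(key(moves), key(base))
  stopifnot(!anyNA(idx))
  base$substage[idx] <- moves$to
  base$source[idx] <- "paper"
  .new_stage_map("paper_modified", "fine", base)
}

#' Coarsen a fine-granularity stage map
#'
#' Collapses a stage map keyed on fine T/M subdescriptors to the coarse
#' clustering granularity. Where all fine cells of a coarse cell agree, the
#' shared sub-stage is kept; where they disagree (e.g. T2aN0M0 vs T2bN0M0),
#' the sub-stage of the lowest subdescriptor is taken and the entry is
#' flagged `source = "ambiguous"`.
#'
#' @param map A fine-granularity `stage_map`.
#' @return A coarse-granularity `stage_map` with `"_coarse"` appended to the
#'   system name.
#' @export
coarsen_stage_map <- function(map) {
  stopifnot(inherits(map, "stage_map"))
  if (map$granularity == "coarse") return(map)
  e <- map$entries
  ck <- coarsen_tnm(e$histology, e$t, e$n, e$m)
  e$ckey <- paste(ck$histology, ck$t, ck$n, ck$m)
  # fine rows within a coarse cell, in subdescriptor order
  e <- e[order(match(e$t, .t_fine), match(e$m, .m_fine)), ]
  sp <- split(e, e$ckey)
  rows <- lapply(sp, function(d) {
    k <- coarsen_tnm(d$histology[1], d$t[1], d$n[1], d$m[1])
    agree <- length(unique(d$substage)) == 1L
    k$substage <- d$substage[1]
    k$source <- if (agree) {
      if (any(d$source == "paper")) "paper" else d$source[1]
    } else "ambiguous"
    k
  })
  out <- do.call(rbind, rows)
  .new_stage_map(paste0(map$system, "_coarse"), "coarse", out)
}

#' Look up stage assignments in a stage map
#'
#' Pure lookup of sub-stage (and stage) labels for TNM categories under a
#' stage map. Queries at coarse granularity against a fine map are resolved
#' through [coarsen_stage_map()]; fine queries against a coarse map are
#' coarsened first. A key absent from the map is an error, never a silent
#' fall-through to another system.
#'
#' @param map A `stage_map`.
#' @inheritParams validate_tnm
#' @return A data.frame with columns `substage`, `stage`, `source`.
#' @examples
#' m <- coarsen_stage_map(stage_map_paper_modified())
#' stage_lookup(m, "ADC", "T1", "N1", "M0")$substage  # "IB"
#' @export
stage_lookup <- function(map, histology, t, n, m) {
  stopifnot(inherits(map, "stage_map"))
  validate_tnm(histology, t, n, m)
  len <- max(length(histology), length(t), length(n), length(m))
  histology <- rep_len(histology, len); t <- rep_len(t, len)
  n <- rep_len(n, len); m <- rep_len(m, len)
  query_coarse <- !any(.is_fine_t(t) | .is_fine_m(m))
  if (map$granularity == "fine" && query_coarse &&
      any(t %in% c("T1", "T2") | m == "M1")) {
    map <- coarsen_stage_map(map)
  }
  if (map$granularity == "coarse") {
    ck <- coarsen_tnm(histology, t, n, m)
    histology <- ck$histology; t <- ck$t; n <- ck$n; m <- ck$m
  }
  e <- map$entries
  idx <- match(paste(histology, t, n, m), paste(e$histology, e$t, e$n, e$m))
  if (anyNA(idx)) {
    miss <- which(is.na(idx))[1]
    stop("no entry in stage map '", map$system, "' for key (",
         histology[miss], ",", t[miss], ",", n[miss], ",", m[miss], ")",
         call. = FALSE)
  }
  data.frame(substage = e$substage[idx], stage = e$stage[idx],
             source = e$source[idx], stringsAsFactors = FALSE)
}

#' Serialize a stage map to JSON
#'
#' Writes `{"system": ..., "granularity": ..., "entries": [...]}` with the
#' provenance (`source`) of every entry preserved.
#'
#' @param map A `stage_map`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_stage_map <- function(map, path) {
  stopifnot(inherits(map, "stage_map"))
  jsonlite::write_json(
    list(system = map$system, granularity = map$granularity,
         entries = map$entries),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a stage map from JSON
#'
#' @param path Path to a file written by [write_stage_map()].
#' @return A `stage_map`.
#' @export
read_stage_map <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  .new_stage_map(x$system, x$granularity, x$entries)
}
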