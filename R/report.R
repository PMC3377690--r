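#' Write the annotated species tree (NHX) for a study report
#'
#' Each leaf carries its verdict as an NHX \code{S=} tag; branches carry
#' their events (\code{EV=}, '+'-separated) and the mutation kinds
#' supporting a pseudogenization (\code{MUT=}); the gene-birth node is
#' tagged \code{B=Y}.  Re-reading the file with
#' \code{read_annotated_tree} recovers the same tags.
#'
#' @param tree \code{species_tree}.
#' @param report \code{study_report} (or any list with \code{verdicts},
#'   \code{events} with birth/events, and optional mutation reports).
#' @param path output file.
#' @export
write_annotated_tree <- function(tree, report, path) {
  phy <- tree$phylo
  n_tip <- tree$n_tip
  verdicts <- report$verdicts
  ev <- report$events
  known <- tree$names
  bad <- setdiff(ev$events$branch, known)
  if (length(bad)) stop("event on unknown branch: ", paste(bad, collapse = ","))
  tag_of <- function(name) {
    parts <- character(0)
    if (name %in% names(verdicts))
      parts <- c(parts, paste0("S=", verdicts[[name]]))
    if (!is.null(ev)) {
      sel <- ev$events$branch == name
      if (any(sel))
        parts <- c(parts, paste0("EV=", paste(ev$events$event[sel],
                                              collapse = "+")))
      mut <- ev$supporting_mutations[[name]]
      if (!is.null(mut) && nrow(mut))
        parts <- c(parts, paste0("MUT=", paste(
          sprintf("%s@%d:%d", mut$kind, mut$exon, mut$position),
          collapse = "+")))
      if (!is.na(ev$birth) && identical(ev$birth, name))
        parts <- c(parts, "B=Y")
    }
    if (!length(parts)) return("")
    paste0("[&&NHX:", paste(parts, collapse = ":"), "]")
  }
  kids <- split(phy$edge[, 2L], phy$edge[, 1L])
  blen_of <- function(nd) {
    e <- match(nd, phy$edge[, 2L])
    if (is.na(e)) NULL else phy$edge.length[e]
  }
  fmt <- function(nd) {
    nm <- tree$names[nd]
    bl <- blen_of(nd)
    bls <- if (is.null(bl)) "" else sprintf(":%.10g", bl)
    if (nd <= n_tip) return(paste0(nm, bls, tag_of(nm)))
    ks <- kids[[as.character(nd)]]
    paste0("(", paste(vapply(ks, fmt, ""), collapse = ","), ")",
           nm, bls, tag_of(nm))
  }
  writeLines(paste0(fmt(n_tip + 1L), ";"), path)
  invisible(path)
}

#' Read an annotated NHX species tree back into its tags
#'
#' @param path file written by \code{write_annotated_tree}.
#' @return list with \code{newick} (the comment-free tree string),
#'   \code{tags}: named list (node name -> named character vector of NHX
#'   tag values).
#' @export
read_annotated_tree <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  tags <- list()
  pat <- "([A-Za-z0-9_.|]+)(:[0-9.eE+-]+)?\\[&&NHX:([^]]*)\\]"
  m <- gregexpr(pat, txt, perl = TRUE)[[1L]]
  if (m[1L] != -1L) {
    for (i in seq_along(m)) {
      piece <- substr(txt, m[i], m[i] + attr(m, "match.length")[i] - 1L)
      name <- sub(pat, "\\1", piece, perl = TRUE)
      body <- sub(pat, "\\3", piece, perl = TRUE)
      kv <- strsplit(body, ":", fixed = TRUE)[[1L]]
      pairs <- strsplit(kv, "=", fixed = TRUE)
      tags[[name]] <- setNames(vapply(pairs, `[`, "", 2L),
                               vapply(pairs, `[`, "", 1L))
    }
  }
  nw <- gsub("\\[[^]]*\\]", "", txt)
  list(newick = nw, tags = tags)
}

#' Write a study report as JSON
#' @param report \code{study_report}.
#' @param path output path.
#' @export
write_report_json <- function(report, path) {
  obj <- report_to_list(report)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

report_to_list <- function(report) {
  ev <- report$events
  list(
    query = report$query,
    ancestor = report$ancestor,
    mode = report$mode,
    seed = report$seed,
    verdicts = as.list(report$verdicts),
    birth = if (is.null(ev) || is.na(ev$birth)) NULL else ev$birth,
    events = if (is.null(ev)) list() else
      lapply(seq_len(nrow(ev$events)), function(i) {
        b <- ev$events$branch[i]
        mut <- ev$supporting_mutations[[b]]
        list(branch = b, event = ev$events$event[i],
             mutations = if (is.null(mut)) list() else
               lapply(seq_len(nrow(mut)), function(k)
                 list(kind = mut$kind[k], exon = mut$exon[k],
                      position = mut$position[k], detail = mut$detail[k])))
      }),
    subfamily_scan = report$subfamily_scan,
    evidence = report$evidence,
    warnings = report$warnings)
}
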