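# Marker panel and immune-subset gating.

#' Marker panel used throughout the workflow
#'
#' The six-marker multiplex immunofluorescence panel: CD3 (T cells), CD4
#' (helper T cells), CD20 (B cells), CD21 (follicular dendritic cells),
#' CD103 (integrin alpha-E, tissue residency) and Bcl-6 (germinal-center
#' program). Marker calls in cell tables are binary (already thresholded
#' upstream by the imaging platform).
#'
#' @return Character vector of the six marker column names.
#' @export
marker_panel <- function() {
  c("CD3", "CD4", "CD20", "CD21", "CD103", "BCL6")
}

#' Default immune-subset gating rules
#'
#' Maps binary marker calls to immune-subset labels. A cell may carry
#' several labels (the subsets are nested, not exclusive): every
#' CD8\eqn{^+} T\eqn{_{RM}} is also a CD8\eqn{^+} T cell and a
#' CD3\eqn{^+} T\eqn{_{RM}}, and every germinal-center B cell is a B cell.
#'
#' Subsets: CD4 T (CD3+CD4+), CD8 T (CD3+CD4-; the panel carries no CD8
#' antibody, so CD8 T cells are gated as CD4-negative T cells), B cell
#' (CD20+), FDC (CD21+), CD3 T_RM (CD3+CD103+), CD4 T_RM (CD3+CD4+CD103+),
#' CD8 T_RM (CD3+CD4-CD103+), GC B (CD20+Bcl-6+).
#'
#' By default the CD4 subsets require CD3 co-positivity so that CD4+
#' myeloid cells are not counted as helper T cells; set
#' `require_cd3_for_cd4 = FALSE` to gate on bare CD4 positivity instead.
#'
#' @param require_cd3_for_cd4 Logical; if `TRUE` (default) the CD4 T and
#'   CD4 T_RM gates also require CD3 positivity.
#' @return A data.frame with columns `subset`, `positive`, `negative`
#'   (semicolon-separated marker lists).
#' @export
default_phenotype_rules <- function(require_cd3_for_cd4 = TRUE) {
  cd4_pos <- if (require_cd3_for_cd4) "CD3;CD4" else "CD4"
  rules <- data.frame(
    subset = c("CD4_T", "CD8_T", "B_cell", "FDC",
               "CD3_TRM", "CD4_TRM", "CD8_TRM", "GC_B"),
    positive = c(cd4_pos, "CD3", "CD20", "CD21",
                 "CD3;CD103", paste0(cd4_pos, ";CD103"), "CD3;CD103",
                 "CD20;BCL6"),
    negative = c("", "CD4", "", "", "", "", "CD4", ""),
    stringsAsFactors = FALSE
  )
  validate_phenotype_rules(rules)
  rules
}

#' Read gating rules from a CSV file
#'
#' The file must have columns `subset`, `positive`, `negative`; marker
#' lists are semicolon-separated, an empty string means no requirement.
#' The default rules ship at
#' `system.file("extdata", "phenotype_rules.csv", package = "tlsmaturity")`.
#'
#' @param path Path to a rules CSV.
#' @return Validated rules data.frame.
#' @export
read_phenotype_rules <- function(path) {
  rules <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  required <- c("subset", "positive", "negative")
  missing <- setdiff(required, names(rules))
  if (length(missing) > 0) {
    stop("rules file ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  }
  rules[required][is.na(rules[required])] <- ""
  validate_phenotype_rules(rules)
  rules
}

split_markers <- function(x) {
  out <- strsplit(x, ";", fixed = TRUE)
  lapply(out, function(m) m[nzchar(m)])
}

validate_phenotype_rules <- function(rules) {
  stopifnot(is.data.frame(rules), nrow(rules) >= 1)
  if (anyDuplicated(rules$subset)) {
    stop("duplicated subset name(s) in rules: ",
         paste(unique(rules$subset[duplicated(rules$subset)]), collapse = ", "))
  }
  pos <- split_markers(rules$positive)
  neg <- split_markers(rules$negative)
  panel <- marker_panel()
  for (i in seq_len(nrow(rules))) {
    unknown <- setdiff(c(pos[[i]], neg[[i]]), panel)
    if (length(unknown) > 0) {
      stop("rule '", rules$subset[i], "' references unknown marker(s): ",
           paste(unknown, collapse = ", "),
           " (panel: ", paste(panel, collapse = ", "), ")")
    }
    clash <- intersect(pos[[i]], neg[[i]])
    if (length(clash) > 0) {
      stop("rule '", rules$subset[i], "' requires marker(s) both positive ",
           "and negative: ", paste(clash, collapse = ", "))
    }
    if (length(pos[[i]]) == 0) {
      stop("rule '", rules$subset[i], "' has no positive marker requirement")
    }
  }
  invisible(rules)
}

check_marker_matrix <- function(cells) {
  panel <- marker_panel()
  missing <- setdiff(panel, names(cells))
  if (length(missing) > 0) {
    stop("cell table lacks marker column(s): ", paste(missing, collapse = ", "))
  }
  m <- as.matrix(cells[panel])
  storage.mode(m) <- "numeric"
  bad <- which(!(m %in% c(0, 1)) | is.na(m))
  if (length(bad) > 0) {
    idx <- arrayInd(bad[1], dim(m))
    id <- if ("cell_id" %in% names(cells)) cells$cell_id[idx[1]] else idx[1]
    stop("marker calls must be 0/1; offending cell_id=", id,
         ", marker=", panel[idx[2]], ", value=", m[bad[1]])
  }
  m
}

#' Subset membership matrix for a cell table
#'
#' Evaluates every gating rule against every cell at once.
#'
#' @param cells Data.frame with the six marker columns (0/1).
#' @param rules Gating rules (see [default_phenotype_rules()]).
#' @return Logical matrix, one row per cell, one column per subset.
#' @export
subset_membership <- function(cells, rules = default_phenotype_rules()) {
  validate_phenotype_rules(rules)
  m <- check_marker_matrix(cells)
  pos <- split_markers(rules$positive)
  neg <- split_markers(rules$negative)
  out <- matrix(FALSE, nrow = nrow(m), ncol = nrow(rules),
                dimnames = list(NULL, rules$subset))
  for (i in seq_len(nrow(rules))) {
    ok <- rep(TRUE, nrow(m))
    for (p in pos[[i]]) ok <- ok & m[, p] == 1
    for (q in neg[[i]]) ok <- ok & m[, q] == 0
    out[, i] <- ok
  }
  out
}

#' Assign subset labels to a single cell
#'
#' @param cell Named vector, list or one-row data.frame carrying the six
#'   binary marker calls.
#' @param rules Gating rules.
#' @return Character vector of subset labels the cell satisfies (possibly
#'   empty); label order follows the rules table, but the set is
#'   independent of rule order.
#' @examples
#' assign_phenotypes(c(CD3 = 1, CD4 = 0, CD20 = 0, CD21 = 0,
#'                     CD103 = 1, BCL6 = 0))
#' @export
assign_phenotypes <- function(cell, rules = default_phenotype_rules()) {
  df <- as.data.frame(as.list(unlist(cell[marker_panel()])))
  names(df) <- marker_panel()
  mem <- subset_membership(df, rules)
  colnames(mem)[mem[1, ]]
}

#' Count immune subsets in one region
#'
#' Counts, for a single TLS or outside field, how many cells satisfy each
#' gating rule, together with the total nucleated-cell count (every row of
#' the cell table is a nucleated, DAPI-positive cell by construction of the
#' upstream segmentation).
#'
#' @param cells Cell table restricted to one region (all rows share one
#'   `region_id` if that column is present).
#' @param rules Gating rules.
#' @return List with `counts` (named integer vector per subset) and
#'   `total` (number of nucleated cells).
#' @export
count_subsets <- function(cells, rules = default_phenotype_rules()) {
  if (nrow(cells) == 0) {
    stop("empty region: subset proportions are undefined for a region ",
         "with zero nucleated cells")
  }
  if ("region_id" %in% names(cells) &&
      length(unique(cells$region_id)) > 1) {
    stop("count_subsets expects cells from a single region; got region_ids: ",
         paste(unique(cells$region_id), collapse = ", "))
  }
  mem <- subset_membership(cells, rules)
  counts <- colSums(mem)
  storage.mode(counts) <- "integer"
  list(counts = counts, total = nrow(cells))
}
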