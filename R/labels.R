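#' Tissue layers traversed during epidural needle placement
#'
#' The five epidural tissue layers in puncture order: fat, interspinous
#' ligament, ligamentum flavum, epidural space, spinal cord. All labels in
#' the package are factors with these levels in this order; the ordinal code
#' of a label is `as.integer(label) - 1L` (0--4).
#'
#' @return Character vector of the five level names in puncture order.
#' @export
#' @examples
#' tissue_labels()
tissue_labels <- function() {
  c("fat", "interspinous_ligament", "ligamentum_flavum",
    "epidural_space", "spinal_cord")
}

#' Coerce to a tissue-label factor
#'
#' @param x Character, integer code (0--4) or factor.
#' @return Factor with the five [tissue_labels()] levels in puncture order.
#' @export
as_tissue_label <- function(x) {
  lv <- tissue_labels()
  if (is.numeric(x)) {
    if (any(x < 0 | x > 4 | x != round(x))) {
      abort("numeric tissue codes must be integers in 0..4")
    }
    return(factor(lv[x + 1L], levels = lv))
  }
  x <- as.character(x)
  bad <- setdiff(unique(x), lv)
  if (length(bad) > 0) {
    abort(paste0("unknown tissue label(s): ", paste(bad, collapse = ", ")))
  }
  factor(x, levels = lv)
}

#' The four binary classification stages of the sequential cascade
#'
#' Each stage discriminates a tissue layer (class 0) from the next-deeper
#' layer (class 1): stage 1 fat vs interspinous ligament, stage 2
#' interspinous ligament vs ligamentum flavum, stage 3 ligamentum flavum vs
#' epidural space, stage 4 epidural space vs spinal cord. Stage k's class-1
#' tissue is stage k+1's class-0 tissue.
#'
#' @return A tibble with columns `stage`, `class0`, `class1`.
#' @export
#' @examples
#' cascade_stages()
cascade_stages <- function() {
  lv <- tissue_labels()
  tibble(
    stage  = 1:4,
    class0 = factor(lv[1:4], levels = lv),
    class1 = factor(lv[2:5], levels = lv)
  )
}

# resolve "stage1".."stage4" / integer to a one-row stage spec
.stage_spec <- function(task) {
  if (is.character(task) && grepl("^stage[1-4]$", task)) {
    k <- as.integer(sub("stage", "", task))
  } else if (is.numeric(task) && task %in% 1:4) {
    k <- as.integer(task)
  } else {
    abort("task must be 'stage1'..'stage4' (or 1..4)")
  }
  cascade_stages()[k, ]
}
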