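#' Split a mask at the median plane
#'
#' Separates a mask into affected and unaffected hemispheres at the image-grid
#' midplane along the declared left-right axis. Voxels with 0-based index
#' `< floor(n/2)` fall on the low side, `>= ceiling(n/2)` on the high side;
#' for odd axis length the exact median-plane slice belongs to neither. With
#' the package's RAS internal ordering the low-index half is the patient's
#' left.
#'
#' @param mask a [binary_mask()].
#' @param affected_side `"left"` or `"right"`.
#' @return A `cvi_hemisphere_split`: list with `affected` and `unaffected`
#'   [binary_mask()]s.
#' @export
split_hemispheres <- function(mask, affected_side) {
  stopifnot(inherits(mask, "cvi_binary_mask"))
  if (!affected_side %in% c("left", "right")) {
    stop(sprintf("unknown affected side '%s' (use \"left\" or \"right\")",
                 affected_side), call. = FALSE)
  }
  axis <- mask$geometry$left_right_axis
  n <- mask$geometry$shape[axis]
  low <- seq_len(floor(n / 2))                     # 0-based < floor(n/2)
  high <- seq.int(ceiling(n / 2) + 1L, n)          # 0-based >= ceil(n/2)
  side_sel <- function(keep) {
    sel <- array(FALSE, dim = mask$geometry$shape)
    idx <- rep(list(quote(expr = )), 3)
    idx[[axis]] <- keep
    sel <- do.call(`[<-`, c(list(sel), idx, list(value = TRUE)))
    out <- mask$data & sel
    dim(out) <- mask$geometry$shape
    out
  }
  left <- side_sel(low)
  right <- side_sel(high)
  if (affected_side == "left") {
    aff <- left; unaff <- right
  } else {
    aff <- right; unaff <- left
  }
  structure(
    list(affected = binary_mask(aff, mask$geometry,
                                label = paste0(mask$label, ":affected")),
         unaffected = binary_mask(unaff, mask$geometry,
                                  label = paste0(mask$label, ":unaffected"))),
    class = "cvi_hemisphere_split"
  )
}

#' @export
print.cvi_hemisphere_split <- function(x, ...) {
  cat(sprintf("<hemisphere split: affected %d voxels, unaffected %d voxels>\n",
              sum(x$affected$data), sum(x$unaffected$data)))
  invisible(x)
}
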