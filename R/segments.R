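# Corpus-callosum segmentation: split the single-slice callosal mask into
# five equal segments per hemisphere (segment 1 at the midline, 5 most
# lateral, ordered by within-mask geodesic distance from the midline), map
# element fields onto segments, and contralateral normalisation.

#' Split a corpus-callosum mask into five segments per hemisphere
#'
#' Voxels of each hemisphere are ranked by geodesic (within-mask, in-plane)
#' distance from the midline crossing and cut into five contiguous groups of
#' equal voxel count; remainder voxels go to the more medial segments, so a
#' 23-voxel hemisphere yields sizes 5,5,5,4,4 from medial to lateral.
#'
#' @param mask A `cc_mask` (see [make_cc_mask()]).
#' @param midline World x-coordinate of the midsagittal plane, mm.
#' @return List with elements `ipsi` and `contra`, each a `segment_set`:
#'   `hemisphere`, `segments` (list of 5 integer vectors of linear voxel
#'   indices, medial to lateral), `n` (per-segment counts).  The hemisphere
#'   at x > midline is labelled ipsilateral (impact side).
#' @export
split_cc <- function(mask, midline = 0) {
  stopifnot(inherits(mask, "cc_mask"))
  idx <- which(mask$mask)
  d <- dim(mask$mask)
  ijk <- arrayInd(idx, d)
  wx <- mask$origin[1] + (ijk[, 1] - 1) * mask$voxel_size[1]
  sides <- list(ipsi = wx > midline, contra = wx < midline)
  for (nm in names(sides)) {
    if (!any(sides[[nm]])) {
      stop("no corpus-callosum voxels on the ", nm, "lateral side of x = ",
           midline)
    }
  }
  out <- lapply(names(sides), function(nm) {
    sel <- sides[[nm]]
    vox <- idx[sel]
    sub <- ijk[sel, , drop = FALSE]
    xs <- abs(wx[sel] - midline)
    # geodesic ordering: BFS over 8-connected in-plane neighbours starting
    # from the most medial voxel(s) of the hemisphere
    n <- length(vox)
    key <- paste(sub[, 1], sub[, 3])
    lookup <- seq_len(n); names(lookup) <- key
    dist <- rep(NA_integer_, n)
    start <- which(xs <= min(xs) + 1e-9)
    dist[start] <- 0L
    frontier <- start
    lvl <- 0L
    offs <- expand.grid(dx = -1:1, dz = -1:1)
    offs <- offs[!(offs$dx == 0 & offs$dz == 0), ]
    while (length(frontier) > 0) {
      lvl <- lvl + 1L
      nxt <- integer(0)
      for (o in seq_len(nrow(offs))) {
        nb_key <- paste(sub[frontier, 1] + offs$dx[o],
                        sub[frontier, 3] + offs$dz[o])
        hit <- lookup[nb_key]
        hit <- hit[!is.na(hit)]
        hit <- hit[is.na(dist[hit])]
        if (length(hit) > 0) {
          dist[hit] <- lvl
          nxt <- c(nxt, hit)
        }
      }
      frontier <- unique(nxt)
    }
    # unreached voxels (disconnected islands) fall back to lateral distance
    dist[is.na(dist)] <- max(dist, na.rm = TRUE) + 1L
    ord <- order(dist, xs, sub[, 3], method = "radix")
    base <- n %/% 5L; rem <- n %% 5L
    sizes <- rep(base, 5L) + c(rep(1L, rem), rep(0L, 5L - rem))
    cuts <- cumsum(c(0L, sizes))
    segments <- lapply(1:5, function(k) {
      sort(vox[ord[(cuts[k] + 1L):cuts[k + 1L]]])
    })
    structure(list(hemisphere = nm, segments = segments,
                   n = vapply(segments, length, 0L)),
              class = "segment_set")
  })
  names(out) <- names(sides)
  out
}

#' @export
print.segment_set <- function(x, ...) {
  cat("segment_set (", x$hemisphere, "): sizes ",
      paste(x$n, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Per-segment mean and SD of a voxel-indexed field
#'
#' @param values Numeric vector of field values whose names are linear voxel
#'   indices (as produced by [strain_on_voxels()]), or a full-grid vector.
#' @param segset A `segment_set`.
#' @param weights Optional weights (same indexing) for volume-weighted means.
#' @return Data frame: hemisphere, segment (1-5), mean, sd, n.
#' @export
segment_means <- function(values, segset, weights = NULL) {
  stopifnot(inherits(segset, "segment_set"))
  fetch <- function(vox) {
    if (!is.null(names(values))) {
      out <- values[as.character(vox)]
      if (any(is.na(names(out)) | is.na(out))) {
        stop("missing field values for voxel(s): ",
             paste(utils::head(vox[is.na(out)], 5), collapse = ", "))
      }
      out
    } else {
      if (max(vox) > length(values)) stop("field shorter than voxel index")
      values[vox]
    }
  }
  rows <- lapply(1:5, function(k) {
    v <- fetch(segset$segments[[k]])
    if (is.null(weights)) {
      data.frame(hemisphere = segset$hemisphere, segment = k,
                 mean = mean(v), sd = stats::sd(v), n = length(v))
    } else {
      w <- if (!is.null(names(weights))) {
        weights[as.character(segset$segments[[k]])]
      } else weights[segset$segments[[k]]]
      mu <- sum(w * v) / sum(w)
      data.frame(hemisphere = segset$hemisphere, segment = k, mean = mu,
                 sd = sqrt(sum(w * (v - mu)^2) / sum(w)), n = length(v))
    }
  })
  do.call(rbind, rows)
}

#' Map a strain field onto corpus-callosum voxels
#'
#' Elements carry their source-voxel identity, so the element value is
#' assigned to the voxel it was meshed from.
#'
#' @param field A `strain_field`.
#' @param quantity `"strain"` or `"strain_rate"`.
#' @return Named numeric vector (names = linear voxel indices).
#' @export
strain_on_voxels <- function(field, quantity = c("strain", "strain_rate")) {
  quantity <- match.arg(quantity)
  vals <- if (quantity == "strain") field$max_strain else field$max_rate
  names(vals) <- field$voxel
  vals
}

#' Segment summaries of strain and strain rate for both hemispheres
#'
#' @param field A `strain_field` from a CCI run.
#' @param segsets Output of [split_cc()].
#' @return Data frame: hemisphere, segment, quantity, mean, sd, n.
#' @export
cc_segment_summary <- function(field, segsets) {
  out <- list()
  for (q in c("strain", "strain_rate")) {
    vals <- strain_on_voxels(field, q)
    for (h in names(segsets)) {
      sm <- segment_means(vals, segsets[[h]])
      sm$quantity <- q
      out[[paste(q, h)]] <- sm
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("hemisphere", "segment", "quantity", "mean", "sd", "n")]
}

#' Contralateral normalisation
#'
#' Expresses an ipsilateral value as percent of the contralateral value
#' (100 percent = equal to the contralateral side).
#'
#' @param ipsi Ipsilateral value(s).
#' @param contra Contralateral value(s), > 0.
#' @return `100 * ipsi / contra`.
#' @export
normalize_contralateral <- function(ipsi, contra) {
  if (any(contra <= 0)) stop("contralateral reference must be > 0")
  100 * ipsi / contra
}

#' Export segment labels as a NIfTI label map
#'
#' Ipsilateral segments are coded 1-5 and contralateral 11-15.
#'
#' @param segsets Output of [split_cc()].
#' @param vol The source [label_volume()] (for grid shape and voxel size).
#' @param path Output NIfTI path.
#' @return `path`, invisibly.
#' @export
write_segment_nifti <- function(segsets, vol, path) {
  arr <- array(0L, dim = dim(vol$data))
  for (k in 1:5) {
    arr[segsets$ipsi$segments[[k]]] <- k
    arr[segsets$contra$segments[[k]]] <- 10L + k
  }
  write_mask_nifti(arr, vol, path)
}
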