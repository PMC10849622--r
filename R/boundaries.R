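#' Layer and boundary naming
#'
#' Macaque V1 layers in pia-to-white-matter order, and the eleven boundaries
#' that delimit them. Boundary `k` is the top of layer `k`; the last boundary
#' (`L6/WM`) is the bottom of the cortex.
#'
#' @export
v1_layers <- c("L1", "L2-3A", "L3B", "L4A", "L4B",
               "L4Ca", "L4Cb", "L5", "L6A", "L6B")

#' @rdname v1_layers
#' @export
v1_boundaries <- c("pia/L1", "L1/L2", "L2-3A/L3B", "L3B/L4A", "L4A/L4B",
                   "L4B/L4C", "L4Ca/L4Cb", "L4Cb/L5", "L5/L6A", "L6A/L6B",
                   "L6/WM")

#' Layer boundaries
#'
#' Ordered named boundaries from the pia to the white matter, on the shared
#' depth axis (origin at the deepest active contact, increasing toward the
#' pia), with per-boundary provenance: `detected` (found by a metric
#' detector), `fallback` (filled by an anatomical rule) or `manual`
#' (user override).
#'
#' Construction validates the ordering invariants: depths strictly decrease
#' from pia to WM (all layer thicknesses positive) and L4Cb is not thicker
#' than L4Ca.
#'
#' @param depth_um named numeric vector, or plain vector of length 11 in
#'   [v1_boundaries] order.
#' @param provenance character vector (recycled), one of `detected`,
#'   `fallback`, `manual`.
#' @return a tibble of class `layer_boundaries` with columns `boundary`,
#'   `depth_um`, `provenance`.
#' @export
layer_boundaries <- function(depth_um, provenance = "manual") {
  if (!is.null(names(depth_um))) {
    stopifnot(all(names(depth_um) %in% v1_boundaries))
    depth_um <- depth_um[v1_boundaries[v1_boundaries %in% names(depth_um)]]
    boundary <- names(depth_um)
  } else {
    stopifnot(length(depth_um) == length(v1_boundaries))
    boundary <- v1_boundaries
  }
  out <- tibble::tibble(
    boundary = boundary,
    depth_um = as.numeric(depth_um),
    provenance = rep_len(as.character(provenance), length(boundary))
  )
  class(out) <- c("layer_boundaries", class(out))
  validate_boundaries(out)
  out
}

#' Validate boundary ordering invariants
#'
#' @param b a `layer_boundaries` tibble (may be partial).
#' @return `b`, invisibly; errors on violation.
#' @export
validate_boundaries <- function(b) {
  ord <- match(b$boundary, v1_boundaries)
  if (anyNA(ord)) {
    stop("unknown boundary name(s): ",
         paste(b$boundary[is.na(ord)], collapse = ", "), call. = FALSE)
  }
  d <- b$depth_um[order(ord)]
  if (any(diff(d) >= 0)) {
    stop("boundaries must be strictly ordered pia -> WM ",
         "(depths strictly decreasing)", call. = FALSE)
  }
  top_ab <- b$depth_um[b$boundary == "L4B/L4C"]
  mid_ab <- b$depth_um[b$boundary == "L4Ca/L4Cb"]
  bot_ab <- b$depth_um[b$boundary == "L4Cb/L5"]
  if (length(top_ab) && length(mid_ab) && length(bot_ab)) {
    if ((mid_ab - bot_ab) > (top_ab - mid_ab) + 1e-9) {
      stop("L4Cb must not be thicker than L4Ca", call. = FALSE)
    }
  }
  invisible(b)
}

#' Per-layer thicknesses
#'
#' @param b a complete `layer_boundaries` object.
#' @return tibble with `layer`, `thickness_um`, `top_um`, `bottom_um`.
#' @export
layer_thicknesses <- function(b) {
  d <- b$depth_um[match(v1_boundaries, b$boundary)]
  names(d) <- v1_boundaries
  layers <- v1_layers
  # L4Ca / L4Cb split L4C at the L4Ca/L4Cb boundary
  tops <- d[c("pia/L1", "L1/L2", "L2-3A/L3B", "L3B/L4A", "L4A/L4B",
              "L4B/L4C", "L4Ca/L4Cb", "L4Cb/L5", "L5/L6A", "L6A/L6B")]
  bots <- d[c("L1/L2", "L2-3A/L3B", "L3B/L4A", "L4A/L4B", "L4B/L4C",
              "L4Ca/L4Cb", "L4Cb/L5", "L5/L6A", "L6A/L6B", "L6/WM")]
  tibble::tibble(layer = layers, thickness_um = as.numeric(tops - bots),
                 top_um = as.numeric(tops), bottom_um = as.numeric(bots))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy layer_boundaries
#' @export
tidy.layer_boundaries <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @method glance layer_boundaries
#' @export
glance.layer_boundaries <- function(x, ...) {
  th <- layer_thicknesses(x)
  tibble::tibble(
    n_boundaries = nrow(x),
    n_detected = sum(x$provenance == "detected"),
    n_fallback = sum(x$provenance == "fallback"),
    n_manual = sum(x$provenance == "manual"),
    cortex_thickness_um = x$depth_um[x$boundary == "pia/L1"] -
      x$depth_um[x$boundary == "L6/WM"],
    l4c_thickness_um = sum(th$thickness_um[th$layer %in% c("L4Ca", "L4Cb")])
  )
}

#' Read / write boundary tables
#'
#' Plain tab-separated files with columns `boundary`, `depth_um`,
#' `provenance`; the same schema is used for manual-override files.
#'
#' @param path file path.
#' @return `read_boundaries()` returns a `layer_boundaries` tibble (partial
#'   tables allowed, ordering still validated on the rows present).
#' @export
read_boundaries <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(all(c("boundary", "depth_um") %in% names(tab)))
  if (is.null(tab$provenance)) tab$provenance <- "manual"
  out <- tibble::as_tibble(tab[c("boundary", "depth_um", "provenance")])
  class(out) <- c("layer_boundaries", class(out))
  validate_boundaries(out)
  out
}

#' @rdname read_boundaries
#' @param b a `layer_boundaries` tibble.
#' @export
write_boundaries <- function(b, path) {
  utils::write.table(tidy(b), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
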