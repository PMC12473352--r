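#' @importFrom rlang abort warn .data
#' @importFrom stats predict rnorm runif setNames sd quantile
#' @importFrom utils head tail
NULL

#' Unilateral working sets of body keypoints
#'
#' The classifier observes one side of the body only.  In the 33-landmark
#' index space the seven working keypoints are shoulder, elbow, wrist,
#' index fingertip, hip, knee and heel; the right-side indices are
#' `{12, 14, 16, 20, 24, 26, 30}` and the left-side indices
#' `{11, 13, 15, 19, 23, 25, 29}`.
#'
#' @format Integer vectors of length 7, named by joint.
#' @export
right_side_keypoints <- c(
  shoulder = 12L, elbow = 14L, wrist = 16L, index = 20L,
  hip = 24L, knee = 26L, heel = 30L
)

#' @rdname right_side_keypoints
#' @export
left_side_keypoints <- c(
  shoulder = 11L, elbow = 13L, wrist = 15L, index = 19L,
  hip = 23L, knee = 25L, heel = 29L
)

# right-index -> left-index map used to mirror group definitions
.lr_map <- setNames(left_side_keypoints, right_side_keypoints)

assert_working_set <- function(working_set) {
  ws <- sort(as.integer(working_set))
  if (identical(ws, sort(unname(right_side_keypoints)))) return("right")
  if (identical(ws, sort(unname(left_side_keypoints)))) return("left")
  abort(paste0(
    "`working_set` must be the right-side set {",
    paste(sort(unname(right_side_keypoints)), collapse = ","),
    "} or the left-side set {",
    paste(sort(unname(left_side_keypoints)), collapse = ","), "}."
  ), class = "reachgcn_invalid_argument")
}

#' Build a chain (path) graph with self-loops and symmetric normalization
#'
#' Nodes are joints of one keypoint group, edges the bones between
#' consecutive joints (1-2-...-V).  The returned object carries the raw
#' adjacency \eqn{A}, the self-loop form \eqn{\tilde A = A + I}, the
#' diagonal degree matrix \eqn{\tilde D} with
#' \eqn{\tilde D_{ii} = \sum_j \tilde A_{ij}}, and the symmetric
#' normalization \eqn{\hat A = \tilde D^{-1/2} \tilde A \tilde D^{-1/2}}
#' used by the spatial graph convolution.
#'
#' @param num_nodes Number of joints in the chain (positive integer).
#' @return An object of class `skeleton_graph`: a list with elements
#'   `num_nodes`, `adjacency`, `adjacency_selfloop`, `degree`,
#'   `normalized`.
#' @examples
#' g <- build_chain_graph(4)
#' diag(g$degree)        # 2 3 3 2
#' g$normalized[1, 1]    # 0.5
#' @export
build_chain_graph <- function(num_nodes) {
  if (length(num_nodes) != 1L || is.na(num_nodes) || num_nodes < 1 ||
      num_nodes != as.integer(num_nodes)) {
    abort("`num_nodes` must be a single positive integer.",
          class = "reachgcn_invalid_argument")
  }
  v <- as.integer(num_nodes)
  a <- matrix(0, v, v)
  if (v > 1L) {
    idx <- seq_len(v - 1L)
    a[cbind(idx, idx + 1L)] <- 1
    a[cbind(idx + 1L, idx)] <- 1
  }
  a_tilde <- a + diag(v)
  deg <- diag(rowSums(a_tilde), v, v)
  d_inv_sqrt <- diag(1 / sqrt(diag(deg)), v, v)
  a_hat <- d_inv_sqrt %*% a_tilde %*% d_inv_sqrt
  # enforce exact symmetry against floating-point round-off
  a_hat <- (a_hat + t(a_hat)) / 2
  structure(
    list(
      num_nodes = v,
      adjacency = a,
      adjacency_selfloop = a_tilde,
      degree = deg,
      normalized = a_hat
    ),
    class = "skeleton_graph"
  )
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat("<skeleton_graph> chain with", x$num_nodes, "nodes,",
      sum(x$adjacency) / 2, "bones\n")
  invisible(x)
}

new_keypoint_group <- function(name, members) {
  stopifnot(length(members) == 4L, !anyDuplicated(members))
  structure(list(name = name, members = as.integer(members)),
            class = "keypoint_group")
}

#' @export
print.keypoint_group <- function(x, ...) {
  cat("<keypoint_group>", x$name, "{", paste(x$members, collapse = ","),
      "}\n")
  invisible(x)
}

#' Group the seven working keypoints into three chains of four
#'
#' The sit-and-reach working set is split into three overlapping groups
#' of four joints each, every group forming a kinematic chain: the upper
#' limb (shoulder, elbow, wrist, index), the trunk chain (shoulder, hip,
#' knee, heel) and the torso bridge (shoulder, elbow, hip, knee).  For
#' the right side these are `{12,14,16,20}`, `{12,24,26,30}` and
#' `{12,14,24,26}`; the left side uses the mirrored indices.
#'
#' @param working_set The seven keypoint indices of one body side (any
#'   order).  Must equal [right_side_keypoints] or
#'   [left_side_keypoints] as a set.
#' @return A list of three `keypoint_group` objects, in the printed
#'   order: `upper_limb`, `trunk_chain`, `torso_bridge`.
#' @examples
#' group_keypoints(c(12, 14, 16, 20, 24, 26, 30))
#' @export
group_keypoints <- function(working_set = right_side_keypoints) {
  side <- assert_working_set(working_set)
  g_right <- list(
    upper_limb   = c(12L, 14L, 16L, 20L),
    trunk_chain  = c(12L, 24L, 26L, 30L),
    torso_bridge = c(12L, 14L, 24L, 26L)
  )
  members <- if (side == "right") {
    g_right
  } else {
    lapply(g_right, function(m) unname(.lr_map[as.character(m)]))
  }
  out <- purrr::imap(members, function(m, nm) new_keypoint_group(nm, m))
  structure(out, class = "keypoint_groups", side = side)
}

#' Pairwise overlap between keypoint groups
#'
#' Reports, for each pair of groups, how many joints they share and
#' whether the pair meets the design guideline of sharing at least two
#' joints.  This is a report, never an error: the printed grouping
#' itself has one pair sharing a single joint.
#'
#' @param groups A list of three `keypoint_group` objects (e.g. from
#'   [group_keypoints()]).
#' @param min_shared Guideline threshold on shared joints (default 2).
#' @return A tibble with columns `group_a`, `group_b`,
#'   `n_shared`, `meets_guideline`.
#' @export
check_group_overlap <- function(groups, min_shared = 2L) {
  if (length(groups) != 3L ||
      !all(vapply(groups, inherits, logical(1), "keypoint_group"))) {
    abort("`groups` must be a list of three keypoint_group objects.",
          class = "reachgcn_invalid_argument")
  }
  pairs <- utils::combn(3L, 2L)
  tibble::tibble(
    group_a = vapply(pairs[1, ], function(i) groups[[i]]$name, character(1)),
    group_b = vapply(pairs[2, ], function(i) groups[[i]]$name, character(1)),
    n_shared = vapply(seq_len(ncol(pairs)), function(k) {
      length(intersect(groups[[pairs[1, k]]]$members,
                       groups[[pairs[2, k]]]$members))
    }, integer(1)),
  ) |>
    dplyr::mutate(meets_guideline = .data$n_shared >= min_shared)
}

#' Export / import group definitions as JSON
#'
#' Group definitions are exchanged as a plain JSON object
#' `{"group_name": [keypoint indices], ...}` so experiments can override
#' the default grouping.
#'
#' @param groups A list of `keypoint_group` objects.
#' @param path File path to write to / read from.
#' @return `write_groups_json()` returns `path` invisibly;
#'   `read_groups_json()` returns a list of `keypoint_group` objects.
#' @export
write_groups_json <- function(groups, path) {
  obj <- purrr::map(groups, "members")
  names(obj) <- purrr::map_chr(groups, "name")
  jsonlite::write_json(obj, path, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_groups_json
#' @export
read_groups_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- purrr::imap(obj, function(m, nm) new_keypoint_group(nm, m))
  structure(out, class = "keypoint_groups")
}
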