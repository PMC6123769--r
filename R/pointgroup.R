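#' Point-group symmetry operators
#'
#' Rotational symmetry acting on Miller indices. Presets cover the point
#' groups needed for the supported space groups: "222" (C222(1), C222, I222),
#' "2" (C2, unique axis b) and "1" (P1). Translational components are
#' irrelevant for intensities and are not represented; systematic absences are
#' the integration stage's concern.
#'
#' @param name One of "1", "2", "222", or a list of 3x3 integer rotation
#'   matrices (must contain the identity and be closed under composition).
#' @return An object of class `point_group` with elements `name` and
#'   `rotations` (list of 3x3 integer matrices).
#' @examples
#' pg <- point_group("222")
#' length(pg$rotations)  # 4
#' @export
point_group <- function(name) {
  if (is.list(name)) {
    rots <- lapply(name, function(m) {
      m <- round(m)
      stopifnot(is.matrix(m), all(dim(m) == c(3L, 3L)), abs(det(m)) == 1)
      storage.mode(m) <- "integer"
      m
    })
    pg <- structure(list(name = "custom", rotations = rots), class = "point_group")
    check_group(pg)
    return(pg)
  }
  id <- diag(3L)
  rots <- switch(as.character(name),
    "1" = list(id),
    # 2-fold along b: (h,k,l) -> (-h, k, -l)
    "2" = list(id, diag(c(-1L, 1L, -1L))),
    # 222: identity plus 2-folds along a, b, c
    "222" = list(id,
                 diag(c(1L, -1L, -1L)),
                 diag(c(-1L, 1L, -1L)),
                 diag(c(-1L, -1L, 1L))),
    stop("unknown point group preset: ", name)
  )
  structure(list(name = as.character(name), rotations = rots), class = "point_group")
}

check_group <- function(pg) {
  rots <- pg$rotations
  keys <- vapply(rots, function(m) paste(m, collapse = ","), "")
  if (!any(keys == paste(diag(3L), collapse = ","))) stop("group lacks identity")
  for (a in rots) for (b in rots) {
    if (!(paste(a %*% b, collapse = ",") %in% keys))
      stop("rotation set not closed under composition")
  }
  invisible(TRUE)
}

#' @export
print.point_group <- function(x, ...) {
  cat(sprintf("Point group %s (%d rotations)\n", x$name, length(x$rotations)))
  invisible(x)
}

is_point_group <- function(x) inherits(x, "point_group")

#' Map a space-group number to its point group
#'
#' Supported space groups: 1 (P1), 5 (C2), 20 (C222(1)), 21 (C222), 23 (I222).
#'
#' @param number Space-group number (International Tables).
#' @return A [point_group()].
#' @export
space_group_point_group <- function(number) {
  pg <- switch(as.character(number),
    "1" = "1", "5" = "2", "20" = "222", "21" = "222", "23" = "222",
    stop("unsupported space group number: ", number,
         " (supported: 1, 5, 20, 21, 23)")
  )
  point_group(pg)
}

point_group_space_group_number <- function(pg) {
  switch(pg$name, "1" = 1L, "2" = 5L, "222" = 20L, 1L)
}

# Lexicographic encoding of hkl triples as exact doubles; |index| < 512.
HKL_BASE <- 1024
encode_hkl <- function(H) {
  ((H[, 1] + 512) * HKL_BASE + (H[, 2] + 512)) * HKL_BASE + (H[, 3] + 512)
}
decode_hkl <- function(code) {
  l <- code %% HKL_BASE
  code <- (code - l) / HKL_BASE
  k <- code %% HKL_BASE
  h <- (code - k) / HKL_BASE
  cbind(h = h - 512, k = k - 512, l = l - 512)
}

#' Map Miller indices to the asymmetric unit
#'
#' Reduces each index triple to a canonical unique-reflection key under the
#' point group. The canonical representative is the lexicographically greatest
#' triple over the symmetry orbit (including Friedel negation). With
#' `anomalous = TRUE` Friedel mates not related by a proper rotation keep
#' opposite signs ("+"/"-"); centric reflections come out "+". With
#' `anomalous = FALSE` the sign is "merged".
#'
#' @param hkl Integer triple or n x 3 matrix.
#' @param ops A [point_group()].
#' @param anomalous Keep Friedel mates separate?
#' @return A data.frame with columns `h, k, l` (canonical triple) and
#'   `friedel` ("+", "-", or "merged").
#' @export
map_to_asu <- function(hkl, ops, anomalous = FALSE) {
  stopifnot(is_point_group(ops))
  H <- as_hkl_matrix(hkl)
  n <- nrow(H)
  if (max(abs(H)) >= 512) stop("Miller indices beyond +/-511 are not supported")
  # candidates: R h for each rotation, and -R h
  best_plus <- rep(-Inf, n)   # best code over proper orbit of +h
  best_minus <- rep(-Inf, n)  # best code over proper orbit of -h
  for (R in ops$rotations) {
    HR <- H %*% t(R)
    cp <- encode_hkl(HR)
    cm <- encode_hkl(-HR)
    best_plus <- pmax(best_plus, cp)
    best_minus <- pmax(best_minus, cm)
  }
  if (anomalous) {
    best <- pmax(best_plus, best_minus)
    friedel <- ifelse(best_plus >= best_minus, "+", "-")
  } else {
    best <- pmax(best_plus, best_minus)
    friedel <- rep("merged", n)
  }
  asu <- decode_hkl(best)
  data.frame(h = asu[, 1], k = asu[, 2], l = asu[, 3], friedel = friedel,
             stringsAsFactors = FALSE)
}
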