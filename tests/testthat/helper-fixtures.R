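# Shared fixtures. Everything is generated in code; slices are memoized per
# (seed, size, ...) so repeated use across tests costs one generation.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

small_params <- function(size = 128L) phantom_params(image_size = size)

# a phantom slice (image + tissue mask)
fix_slice <- function(seed = 1L, size = 128L) {
  memo(sprintf("slice_%d_%d", seed, size), generate_slice(small_params(size), seed = seed))
}

# a lesioned, normalized phantom with its injection ground truth
fix_lesioned <- function(seed = 1L, n = 5L, d = c(3, 6), contrast = 40, size = 128L) {
  memo(sprintf("les_%d_%d_%s_%s_%d", seed, n, paste(d, collapse = "-"), contrast, size), {
    sl <- fix_slice(seed, size)
    inj <- inject_lesions(sl$image, sl$mask,
                          lesion_spec(n, diameter_px = d, contrast = contrast),
                          seed = seed + 1000L)
    list(image = inj$image, norm = auto_contrast(inj$image),
         boxes = inj$boxes, mask = sl$mask)
  })
}

# uniform background with a rectangular bright streak (for exclusion rules)
streak_image <- function(h, w, value = 40, size = 64L, base = 100) {
  img <- matrix(base, size, size)
  r0 <- size %/% 2L; c0 <- size %/% 2L
  img[r0:(r0 + h - 1L), c0:(c0 + w - 1L)] <- base + value
  image_slice(img)
}

# hand-built lesion patch: square bump with a round-ish mask
toy_patch <- function(side = 5L, value = 200, base = 120, id = "toy") {
  patch <- matrix(value, side, side)
  mask <- matrix(TRUE, side, side)
  lesion_patch(patch, mask, source_id = id,
               bbox_in_source = bbox(0, 0, side, side),
               centroid = c(x = side / 2, y = side / 2))
}

# exhaustive maximum-cardinality matching (oracle for greedy matching)
oracle_max_matching <- function(elig) {
  # elig: logical detection x truth eligibility matrix
  nd <- nrow(elig); nt <- ncol(elig)
  best <- 0L
  recurse <- function(i, used) {
    if (i > nd) return(0L)
    top <- recurse(i + 1L, used) # skip detection i
    for (j in seq_len(nt)) {
      if (elig[i, j] && !used[j]) {
        used2 <- used; used2[j] <- TRUE
        top <- max(top, 1L + recurse(i + 1L, used2))
      }
    }
    top
  }
  recurse(1L, rep(FALSE, nt))
}

# enumeration oracle for the exact Mann-Whitney p-value (tie-free samples)
oracle_mw_p <- function(x, y) {
  u_stat <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  pool <- c(x, y)
  n1 <- length(x)
  mid <- n1 * length(y) / 2
  obs <- u_stat(x, y)
  us <- apply(utils::combn(length(pool), n1), 2,
              function(ix) u_stat(pool[ix], pool[-ix]))
  mean(abs(us - mid) >= abs(obs - mid) - 1e-12)
}

# BFS flood fill per connected region; returns per-label total areas
oracle_flood_areas <- function(lab) {
  visited <- matrix(FALSE, nrow(lab), ncol(lab))
  areas <- integer(0)
  nr <- nrow(lab); nc <- ncol(lab)
  for (start in which(!visited)) {
    if (visited[start]) next
    target <- lab[start]
    frontier <- start
    visited[start] <- TRUE
    area <- 0L
    while (length(frontier) > 0L) {
      area <- area + length(frontier)
      rows <- ((frontier - 1L) %% nr) + 1L
      cols <- ((frontier - 1L) %/% nr) + 1L
      nbr <- c(
        ifelse(rows > 1L, frontier - 1L, NA),
        ifelse(rows < nr, frontier + 1L, NA),
        ifelse(cols > 1L, frontier - nr, NA),
        ifelse(cols < nc, frontier + nr, NA)
      )
      nbr <- unique(nbr[!is.na(nbr)])
      nbr <- nbr[!visited[nbr] & lab[nbr] == target]
      visited[nbr] <- TRUE
      frontier <- nbr
    }
    key <- as.character(target)
    areas[key] <- (if (key %in% names(areas)) areas[key] else 0L) + area
  }
  areas
}
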