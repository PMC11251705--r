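# Fixtures built in code; no data files.

# A small image with a known structure: zero background, a constant body
# block, and an optional hotter insert.
blockImage <- function(bodyLevel = 1000, insertLevel = NULL,
                       dims = c(16L, 16L, 16L), modality = "AC",
                       metadata = list()) {
  v <- array(0, dims)
  v[5:12, 5:12, 5:12] <- bodyLevel
  # insert is 12.5% of the body so upper percentiles >= 90 reach it
  if (!is.null(insertLevel)) v[5:8, 5:8, 5:8] <- insertLevel
  PetImage(v, modality, metadata)
}

fullMask <- function(image, organ = "liver") {
  OrganMask(array(TRUE, dim(voxels(image))), organ)
}

constImage <- function(value, dims = c(4L, 4L, 4L), modality = "AC") {
  PetImage(array(value, dims), modality)
}

# Cohort with a planted stability cutoff: the lower 95% of body-region
# intensities are identical across subjects, the top 5% carry an
# independent per-subject gain with CV ~0.5 (truncated lognormal).
# Liver and spleen masks are carved from the stable compartment.
plantedCutoffCohort <- function(n, seed) {
  dims <- c(24L, 24L, 24L)
  N <- prod(dims)
  nBody <- 3456L
  nVol <- round(0.05 * nBody)
  nStable <- nBody - nVol
  stable <- seq(2000, 3000, length.out = nStable)
  volBase <- seq(12000, 24000, length.out = nVol)
  liverIdx <- 2900:3099
  spleenIdx <- 3150:3282
  set.seed(seed)
  images <- liver <- spleen <- vector("list", n)
  for (i in seq_len(n)) {
    g <- exp(0.47 * max(-2, min(2, stats::rnorm(1))))
    v <- numeric(N)
    v[seq_len(nStable)] <- stable
    v[(nStable + 1L):nBody] <- g * volBase
    lm <- array(FALSE, dims); lm[liverIdx] <- TRUE
    sm <- array(FALSE, dims); sm[spleenIdx] <- TRUE
    images[[i]] <- PetImage(array(v, dims), "AC")
    liver[[i]] <- OrganMask(lm, "liver")
    spleen[[i]] <- OrganMask(sm, "spleen")
  }
  list(images = images, liver = liver, spleen = spleen)
}

pairImages <- function(pairs)
  lapply(pairs, function(p) list(subjectImage(p[[1]]), subjectImage(p[[2]])))

pairMasks <- function(pairs, organ)
  lapply(pairs, function(p) list(subjectMask(p[[1]], organ),
                                 subjectMask(p[[2]], organ)))
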