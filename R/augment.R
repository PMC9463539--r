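# ImageNet channel statistics used by the 3 x 224 x 224 pipeline
IMAGENET_MEAN <- c(0.485, 0.456, 0.406)
IMAGENET_SD <- c(0.229, 0.224, 0.225)

resize_bilinear <- function(px, w, h) {
  as.matrix(EBImage::resize(px, w = w, h = h))
}

# replicate a grayscale 224x224 matrix to 3 channels and normalize,
# returning a (3, 224, 224) array
channels_normalize <- function(px) {
  out <- array(0, c(3L, nrow(px), ncol(px)))
  for (c_ in 1:3) out[c_, , ] <- (px - IMAGENET_MEAN[c_]) / IMAGENET_SD[c_]
  out
}

#' Training augmentation pipeline (residual-backbone scale)
#'
#' Reproduces the standard radiograph training pipeline: the grayscale input
#' is resized to 300 x 300, randomly resize-cropped to 224 x 224, flipped
#' horizontally with probability 0.5, affine-transformed (rotation and shear)
#' with probability `p_affine`, brightness/contrast-jittered with probability
#' `p_color`, replicated to 3 channels and normalized with the ImageNet
#' channel statistics. All randomness uses the current R RNG stream, so a
#' fixed seed reproduces the augmentation exactly.
#'
#' The toy 64 x 64 training path does not use this pipeline; it exists for
#' full-scale (224 x 224) configurations.
#'
#' @param pixels grayscale matrix in \[0, 1\].
#' @param p_affine probability of applying rotation + shear.
#' @param p_color probability of applying brightness/contrast jitter.
#' @param hflip allow random horizontal flip.
#' @param crop `"random"` for random resized crop, `"center"` for the
#'   deterministic center crop.
#' @return numeric array of dimension `c(3, 224, 224)`.
#' @export
augment_train <- function(pixels, p_affine = 0.5, p_color = 0.5,
                          hflip = TRUE, crop = c("random", "center")) {
  crop <- match.arg(crop)
  px <- resize_bilinear(pixels, 300L, 300L)
  if (crop == "random") {
    area <- runif(1, 0.5, 1) * 300^2
    aspect <- exp(runif(1, log(3 / 4), log(4 / 3)))
    cw <- min(300L, round(sqrt(area * aspect)))
    ch <- min(300L, round(sqrt(area / aspect)))
    x0 <- sample.int(300L - cw + 1L, 1L)
    y0 <- sample.int(300L - ch + 1L, 1L)
    px <- px[x0:(x0 + cw - 1L), y0:(y0 + ch - 1L)]
    px <- resize_bilinear(px, 224L, 224L)
  } else {
    px <- center_crop(px, 224L)
  }
  if (hflip && runif(1) < 0.5) px <- px[rev(seq_len(nrow(px))), ]
  if (p_affine > 0 && runif(1) < p_affine) {
    angle <- runif(1, -10, 10)
    shear <- runif(1, -8, 8) * pi / 180
    th <- angle * pi / 180
    # rotation + shear about the image center
    rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    shm <- matrix(c(1, 0, tan(shear), 1), 2)
    m2 <- rot %*% shm
    ctr <- (224 + 1) / 2
    off <- c(ctr, ctr) - m2 %*% c(ctr, ctr)
    m <- rbind(t(m2), as.vector(off))  # 3 x 2 as expected by EBImage::affine
    px <- as.matrix(EBImage::affine(px, m, bg.col = 0))
  }
  if (p_color > 0 && runif(1) < p_color) {
    brightness <- runif(1, -0.15, 0.15)
    contrast <- runif(1, 0.8, 1.2)
    px <- clamp01((px - 0.5) * contrast + 0.5 + brightness)
  }
  channels_normalize(px)
}

center_crop <- function(px, size) {
  o <- (nrow(px) - size) %/% 2
  px[(o + 1):(o + size), (o + 1):(o + size)]
}

#' Deterministic evaluation preprocessing (residual-backbone scale)
#'
#' Resize to 300 x 300, center crop to 224 x 224, replicate to 3 channels,
#' and normalize with the ImageNet channel statistics. Fully deterministic.
#'
#' @param pixels grayscale matrix in \[0, 1\].
#' @return numeric array of dimension `c(3, 224, 224)`.
#' @export
preprocess_eval <- function(pixels) {
  px <- resize_bilinear(pixels, 300L, 300L)
  channels_normalize(center_crop(px, 224L))
}
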