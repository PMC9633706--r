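# Published WGAN generator/critic architectures, desk-scale variants, the
# VGG16 transfer classifier, and a small stand-in classifier.

#' Generator architecture
#'
#' The published generator: a 50-dimensional standard-normal latent input,
#' a bias-free dense layer to 100,352 units, batch normalization, ELU
#' (alpha 0.2), reshape to 14x14x512, four upsample-by-2 stages with 3x3
#' bias-free convolutions (128, 128, 128, then 1 filter), a final
#' per-channel batch normalization, tanh, and a 7-pixel crop from 224x224
#' down to the 210x210 output. Total parameters 6,304,900 of which
#' 6,104,194 are trainable (the batch-norm moving statistics are not).
#'
#' @param latent_dim Latent input dimension.
#' @param seed_hw Side length of the post-dense feature map.
#' @param seed_channels Channels of the post-dense feature map.
#' @param filters Filters of the three intermediate convolution stages.
#' @param crop Pixels cropped per side after the last upsample stage.
#' @return An [arch_spec()]; output side is `seed_hw * 16 - 2 * crop`.
#' @export
generator_spec <- function(latent_dim = 50, seed_hw = 14,
                           seed_channels = 512, filters = 128, crop = 7) {
  layers <- list(
    layer("dense", units = seed_hw^2 * seed_channels, use_bias = FALSE),
    layer("batchnorm"),
    layer("elu", alpha = 0.2),
    layer("reshape", shape = c(seed_hw, seed_hw, seed_channels)))
  for (i in 1:3) {
    layers <- c(layers, list(
      layer("upsample", factor = 2L),
      layer("conv", filters = filters, kernel = 3L, stride = 1L,
            padding = "same", use_bias = FALSE),
      layer("elu", alpha = 0.2)))
  }
  layers <- c(layers, list(
    layer("upsample", factor = 2L),
    layer("conv", filters = 1L, kernel = 3L, stride = 1L, padding = "same",
          use_bias = FALSE),
    layer("batchnorm"),
    layer("tanh"),
    layer("crop", p = as.integer(crop))))
  arch_spec("generator", latent_dim, layers)
}

#' Critic (discriminator) architecture
#'
#' The published critic: 210x210x1 input, 2-pixel zero padding, five
#' stride-2 5x5 convolutions (64, 128, 256, 312, 422 filters, biases,
#' 'same' padding — forced by the printed intermediate shapes
#' 214-107-54-27-14-7), ELU (alpha 0.2) activations, dropout 0.3 after the
#' second and third convolutions, flatten to 20,678 features, dropout 0.2,
#' and a single linear output unit (the Wasserstein critic score). Total
#' parameters 6,335,861, all trainable.
#'
#' @param input_size Input side length.
#' @param filters Filter counts of the five convolution stages.
#' @return An [arch_spec()].
#' @export
critic_spec <- function(input_size = 210,
                        filters = c(64, 128, 256, 312, 422)) {
  stopifnot(length(filters) == 5)
  layers <- list(layer("zeropad", p = 2L))
  drop_after <- c(NA, 0.3, 0.3, NA, NA)
  for (i in 1:5) {
    layers <- c(layers, list(
      layer("conv", filters = as.integer(filters[i]), kernel = 5L,
            stride = 2L, padding = "same", use_bias = TRUE),
      layer("elu", alpha = 0.2)))
    if (!is.na(drop_after[i]))
      layers <- c(layers, list(layer("dropout", rate = drop_after[i])))
  }
  layers <- c(layers, list(
    layer("flatten"),
    layer("dropout", rate = 0.2),
    layer("dense", units = 1L, use_bias = TRUE)))
  arch_spec("critic", c(input_size, input_size, 1L), layers)
}

#' Desk-scale WGAN architecture variants
#'
#' Same topology as the published networks (upsample/conv generator with a
#' crop, strided 'same'-padded critic with dropout) at 64x64 with reduced
#' filter counts, for CPU-scale smoke training and tests.
#'
#' @param latent_dim Latent dimension.
#' @return An [arch_spec()].
#' @export
scaled_generator_spec <- function(latent_dim = 50) {
  generator_spec(latent_dim = latent_dim, seed_hw = 5, seed_channels = 64,
                 filters = 32, crop = 8)
}

#' @rdname scaled_generator_spec
#' @export
scaled_critic_spec <- function() {
  critic_spec(input_size = 64, filters = c(8, 16, 32, 32, 48))
}

#' VGG16 transfer-learning classifier architecture
#'
#' The VGG16 convolutional base (13 convolutions in five blocks, input
#' sized so the base emits a 6x6x512 map, i.e. 192x192x3), followed by
#' flatten (18,432), a 256-unit ELU dense layer and a single sigmoid
#' output. Convolution blocks 1-4 are frozen; block 5 and the dense head
#' are trainable — the freeze split forced by the printed non-trainable
#' count 7,635,264 (exactly the block 1-4 parameters). Totals: 19,433,793
#' parameters, 11,798,529 trainable.
#'
#' @param input_size Input side length (default 192 yields the 6x6x512 map).
#' @return An [arch_spec()] with per-layer `trainable` flags.
#' @export
transfer_spec <- function(input_size = 192) {
  blocks <- list(c(64, 64), c(128, 128), c(256, 256, 256),
                 c(512, 512, 512), c(512, 512, 512))
  layers <- list()
  for (b in seq_along(blocks)) {
    frozen <- b <= 4
    for (f in blocks[[b]]) {
      layers <- c(layers, list(
        layer("conv", filters = as.integer(f), kernel = 3L, stride = 1L,
              padding = "same", use_bias = TRUE, trainable = !frozen),
        layer("elu", alpha = 1)))
    }
    layers <- c(layers, list(layer("maxpool", size = 2L)))
  }
  layers <- c(layers, list(
    layer("flatten"),
    layer("dense", units = 256L, use_bias = TRUE),
    layer("elu", alpha = 1),
    layer("dense", units = 1L, use_bias = TRUE),
    layer("sigmoid")))
  arch_spec("vgg16_transfer", c(input_size, input_size, 3L), layers)
}

#' Small stand-in classifier for desk-scale experiments
#'
#' A compact strided CNN with a sigmoid binary output, used where the
#' VGG16 transfer model would be used at full scale.
#'
#' @param input_size Input side length.
#' @return An [arch_spec()].
#' @export
small_classifier_spec <- function(input_size = 32) {
  arch_spec("small_classifier", c(input_size, input_size, 1L), list(
    layer("conv", filters = 8L, kernel = 3L, stride = 2L, padding = "same",
          use_bias = TRUE),
    layer("elu", alpha = 1),
    layer("conv", filters = 16L, kernel = 3L, stride = 2L, padding = "same",
          use_bias = TRUE),
    layer("elu", alpha = 1),
    layer("flatten"),
    layer("dense", units = 32L, use_bias = TRUE),
    layer("elu", alpha = 1),
    layer("dense", units = 1L, use_bias = TRUE)))
}

#' Build the generator network
#'
#' Materializes the generator of [generator_spec()]; the resulting network
#' maps latent vectors to images in \[-1, 1\].
#'
#' @param spec Architecture spec (default: the published full-size one).
#' @param seed Weight-initialization seed.
#' @return An `nn_network`.
#' @export
build_generator <- function(spec = generator_spec(), seed = 1L) {
  build_network(spec, seed = seed)
}

#' Build the critic network
#'
#' @param spec Architecture spec (default: the published full-size one).
#' @param seed Weight-initialization seed.
#' @return An `nn_network`.
#' @export
build_critic <- function(spec = critic_spec(), seed = 1L) {
  build_network(spec, seed = seed)
}

#' Build the VGG16 transfer classifier
#'
#' @param spec Architecture spec from [transfer_spec()].
#' @param materialize If `FALSE` (default) return the spec with its
#'   parameter counts only; if `TRUE` initialize all 19.4M weights
#'   (randomly — pretrained ImageNet weights are not bundled).
#' @param seed Weight-initialization seed.
#' @return An `nn_network` (materialized) or the `arch_spec`.
#' @export
build_transfer_model <- function(spec = transfer_spec(), materialize = FALSE,
                                 seed = 1L) {
  if (materialize) build_network(spec, seed = seed) else spec
}
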