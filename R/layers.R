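#' @useDynLib lodgeseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---- parameter initialisation -------------------------------------------

#' Fan-based uniform initialisation
#'
#' Draws weights from U(-1/sqrt(fan_in), 1/sqrt(fan_in)), the conventional
#' default for convolution and linear layers when no pretrained values are
#' available.  Biases use the same bound.
#'
#' @param dims integer vector of array dimensions.
#' @param fan_in number of input connections per output unit.
#' @return numeric array of dimension `dims`.
#' @keywords internal
init_fan_uniform <- function(dims, fan_in) {
  bound <- 1 / sqrt(max(fan_in, 1))
  array(stats::runif(prod(dims), -bound, bound), dim = dims)
}

init_conv <- function(kh, kw, cin, cout) {
  fan_in <- kh * kw * cin
  list(w = init_fan_uniform(c(kh, kw, cin, cout), fan_in),
       b = as.numeric(init_fan_uniform(cout, fan_in)))
}

init_linear <- function(cin, cout) {
  list(w = init_fan_uniform(c(cin, cout), cin),
       b = as.numeric(init_fan_uniform(cout, cin)))
}

# ---- convolution ---------------------------------------------------------

# "same"-style padding for odd kernels at any atrous rate.
conv_pad <- function(k, dilation) dilation * (k - 1) %/% 2

#' 2-D convolution forward pass
#'
#' @param x numeric array `H x W x Cin`.
#' @param w kernel array `kh x kw x Cin x Cout`.
#' @param b bias vector of length `Cout`, or NULL.
#' @param stride positive integer stride.
#' @param dilation atrous rate (1 = standard convolution).
#' @return list with the output array `y` and a cache for the backward pass.
#' @keywords internal
conv_forward <- function(x, w, b = NULL, stride = 1L, dilation = 1L) {
  dw <- dim(w)
  stopifnot(length(dim(x)) == 3L, length(dw) == 4L)
  if (dim(x)[3] != dw[3])
    stop("conv: input has ", dim(x)[3], " channels but kernel expects ", dw[3])
  pad <- conv_pad(dw[1], dilation)
  # pointwise stride-1 convolutions skip im2col entirely
  cols <- if (dw[1] == 1L && dw[2] == 1L && stride == 1L)
    matrix(x, nrow = dim(x)[1] * dim(x)[2], ncol = dw[3])
  else cpp_im2col(x, dw[1], dw[2], stride, dilation, pad)
  wmat <- matrix(w, nrow = dw[1] * dw[2] * dw[3], ncol = dw[4])
  ymat <- cols %*% wmat
  if (!is.null(b)) ymat <- sweep(ymat, 2L, b, "+")
  ho <- conv_out_size(dim(x)[1], dw[1], stride, dilation, pad)
  wo <- conv_out_size(dim(x)[2], dw[2], stride, dilation, pad)
  y <- array(ymat, dim = c(ho, wo, dw[4]))
  list(y = y, cache = list(cols = cols, dimx = dim(x), w = w,
                           stride = stride, dilation = dilation, pad = pad))
}

conv_out_size <- function(n, k, stride, dilation, pad) {
  (n + 2L * pad - (dilation * (k - 1L) + 1L)) %/% stride + 1L
}

#' 2-D convolution backward pass
#'
#' @param gy gradient of the loss w.r.t. the convolution output.
#' @param cache cache returned by [conv_forward()].
#' @return list with `gx` (input gradient), `gw`, `gb`.
#' @keywords internal
conv_backward <- function(gy, cache) {
  dw <- dim(cache$w)
  gymat <- matrix(gy, ncol = dw[4])
  wmat <- matrix(cache$w, nrow = dw[1] * dw[2] * dw[3], ncol = dw[4])
  gw <- array(crossprod(cache$cols, gymat), dim = dw)
  gb <- colSums(gymat)
  gcols <- tcrossprod(gymat, wmat)
  gx <- if (dw[1] == 1L && dw[2] == 1L && cache$stride == 1L)
    array(gcols, dim = cache$dimx)
  else cpp_col2im(gcols, cache$dimx[1], cache$dimx[2], cache$dimx[3],
                  dw[1], dw[2], cache$stride, cache$dilation, cache$pad)
  list(gx = gx, gw = gw, gb = gb)
}

# ---- pointwise nonlinearity ---------------------------------------------

relu_forward <- function(x) list(y = pmax(x, 0), mask = x > 0)
relu_backward <- function(gy, mask) gy * mask

# ---- bilinear resampling -------------------------------------------------

#' Bilinear resize of an `H x W x C` array
#'
#' Corner-aligned bilinear interpolation, used to restore logits to label
#' resolution.  [bilinear_resize_grad()] is its exact adjoint.
#'
#' @param x numeric array `H x W x C`.
#' @param out_h,out_w output spatial size.
#' @return resized array `out_h x out_w x C`.
#' @export
bilinear_resize <- function(x, out_h, out_w) {
  stopifnot(length(dim(x)) == 3L, out_h >= 1L, out_w >= 1L)
  y <- cpp_bilinear_resize(x, as.integer(out_h), as.integer(out_w))
  array(y, dim = c(out_h, out_w, dim(x)[3]))
}

#' @rdname bilinear_resize
#' @param gy gradient array at the output resolution.
#' @param in_h,in_w input spatial size to scatter the gradient back to.
#' @export
bilinear_resize_grad <- function(gy, in_h, in_w) {
  gx <- cpp_bilinear_resize_grad(gy, as.integer(in_h), as.integer(in_w))
  array(gx, dim = c(in_h, in_w, dim(gy)[3]))
}
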