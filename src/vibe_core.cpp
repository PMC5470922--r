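#include <Rcpp.h>
using namespace Rcpp;

// Per-pixel sample model layout: numeric array dim (H, W, k, N), column-major.
// All RNG goes through R's stream (unif_rand), so set.seed() on the R side
// makes every trajectory reproducible. Draw order is fixed: raster order over
// pixels (rows, then columns within a row), and within a background pixel
// (self coin, self slot, neighbor coin, neighbor index, neighbor slot);
// slot/index draws only happen when the corresponding coin fires.

static inline R_xlen_t midx(int H, int W, int k, int i, int j, int c, int s) {
  return (R_xlen_t)i + (R_xlen_t)H * (j + (R_xlen_t)W * (c + (R_xlen_t)k * s));
}

static inline int rint_below(int n) {
  int v = (int)(unif_rand() * n);
  return v >= n ? n - 1 : v;
}

// [[Rcpp::export]]
NumericVector cpp_init_model(NumericVector frame, int n_samples) {
  IntegerVector d = frame.attr("dim");
  if (d.size() != 3) stop("frame must be an H x W x k array");
  int H = d[0], W = d[1], k = d[2];
  NumericVector model((R_xlen_t)H * W * k * n_samples);
  model.attr("dim") = IntegerVector::create(H, W, k, n_samples);
  int ni[9], nj[9];
  for (int i = 0; i < H; ++i) {
    for (int j = 0; j < W; ++j) {
      // in-bounds 8-neighborhood plus the pixel itself
      int cnt = 0;
      for (int di = -1; di <= 1; ++di)
        for (int dj = -1; dj <= 1; ++dj) {
          int ii = i + di, jj = j + dj;
          if (ii >= 0 && ii < H && jj >= 0 && jj < W) { ni[cnt] = ii; nj[cnt] = jj; ++cnt; }
        }
      for (int s = 0; s < n_samples; ++s) {
        int p = rint_below(cnt);
        for (int c = 0; c < k; ++c)
          model[midx(H, W, k, i, j, c, s)] =
            frame[(R_xlen_t)ni[p] + (R_xlen_t)H * (nj[p] + (R_xlen_t)W * c)];
      }
    }
  }
  return model;
}

// [[Rcpp::export]]
int cpp_count_matches(NumericVector value, NumericMatrix samples, double radius) {
  int k = value.size();
  if (samples.ncol() != k) stop("value and samples disagree on dimensionality");
  double r2 = radius * radius;
  int count = 0;
  for (int s = 0; s < samples.nrow(); ++s) {
    double d2 = 0.0;
    for (int c = 0; c < k; ++c) {
      double d = samples(s, c) - value[c];
      d2 += d * d;
    }
    if (d2 < r2) ++count;  // strict Euclidean distance < radius
  }
  return count;
}

static inline bool is_background(const double* M, const double* val,
                                 int H, int W, int k, int N, int i, int j,
                                 double r2, int lambda) {
  int matches = 0;
  for (int s = 0; s < N && matches < lambda; ++s) {
    double d2 = 0.0;
    for (int c = 0; c < k; ++c) {
      double d = M[midx(H, W, k, i, j, c, s)] - val[c];
      d2 += d * d;
    }
    if (d2 < r2) ++matches;
  }
  return matches >= lambda;
}

// Background-branch update: with prob 1/phi replace a random own sample (and,
// when a depth model is attached, refresh MD(x) on the same coin); with an
// independent prob 1/phi replace a random sample of a random in-bounds
// 8-neighbor with the current pixel's value.
static inline void update_background_pixel(double* M, const double* val,
                                           int H, int W, int k, int N,
                                           int i, int j, double phi_inv,
                                           double* MD, double md_val) {
  if (unif_rand() < phi_inv) {
    int s = rint_below(N);
    for (int c = 0; c < k; ++c) M[midx(H, W, k, i, j, c, s)] = val[c];
    if (MD) MD[(R_xlen_t)i + (R_xlen_t)H * j] = md_val;
  }
  if (unif_rand() < phi_inv) {
    int ni[8], nj[8], cnt = 0;
    for (int di = -1; di <= 1; ++di)
      for (int dj = -1; dj <= 1; ++dj) {
        if (di == 0 && dj == 0) continue;
        int ii = i + di, jj = j + dj;
        if (ii >= 0 && ii < H && jj >= 0 && jj < W) { ni[cnt] = ii; nj[cnt] = jj; ++cnt; }
      }
    int p = rint_below(cnt);
    int s = rint_below(N);
    for (int c = 0; c < k; ++c) M[midx(H, W, k, ni[p], nj[p], c, s)] = val[c];
  }
}

// [[Rcpp::export]]
NumericVector cpp_stochastic_update(NumericVector model, int row, int col,
                                    NumericVector value, int phi) {
  IntegerVector d = model.attr("dim");
  int H = d[0], W = d[1], k = d[2], N = d[3];
  if (row < 0 || row >= H || col < 0 || col >= W) stop("position out of bounds");
  if (value.size() != k) stop("value dimensionality does not match model");
  NumericVector out = clone(model);
  update_background_pixel(REAL(out), REAL(value), H, W, k, N, row, col,
                          1.0 / phi, (double*)0, 0.0);
  return out;
}

// Shared frame-loop driver. prox_frames non-null => DEVB: the ghost test
// (depth-model value minus current proximity > tau, both on the same scale)
// reclassifies foreground pixels and runs the background-branch model update;
// the depth model itself is refreshed only in the true background branch, on
// the self-update coin.
static List run_loop(List frames, int N, double radius, int lambda, int phi,
                     Nullable<List> prox_frames_, double tau) {
  int T = frames.size();
  if (T < 1) stop("at least one frame is required");
  NumericVector f0 = frames[0];
  IntegerVector d = f0.attr("dim");
  if (d.size() != 3) stop("frames must be H x W x k arrays");
  int H = d[0], W = d[1], k = d[2];
  bool depth = prox_frames_.isNotNull();
  List prox_frames;
  if (depth) prox_frames = List(prox_frames_);

  NumericVector model = cpp_init_model(f0, N);
  double* M = REAL(model);
  NumericMatrix depth_model(H, W);
  double* MD = depth ? REAL(depth_model) : (double*)0;
  if (depth) {
    NumericMatrix p0 = prox_frames[0];
    for (R_xlen_t q = 0; q < (R_xlen_t)H * W; ++q) MD[q] = p0[q];
  }

  double r2 = radius * radius, phi_inv = 1.0 / phi;
  List masks(T);
  IntegerVector ghost_counts(T);
  std::vector<double> val(k);

  for (int t = 0; t < T; ++t) {
    NumericVector fr = frames[t];
    IntegerVector df = fr.attr("dim");
    if (df[0] != H || df[1] != W || df[2] != k) stop("frame %d has mismatched shape", t + 1);
    const double* F = REAL(fr);
    const double* P = 0;
    if (depth) {
      NumericMatrix pm = prox_frames[t];
      if (pm.nrow() != H || pm.ncol() != W) stop("proximity frame %d has mismatched shape", t + 1);
      P = REAL(pm);
    }
    LogicalMatrix mask(H, W);
    int ghosts = 0;
    for (int i = 0; i < H; ++i) {
      for (int j = 0; j < W; ++j) {
        for (int c = 0; c < k; ++c)
          val[c] = F[(R_xlen_t)i + (R_xlen_t)H * (j + (R_xlen_t)W * c)];
        double cur_p = depth ? P[(R_xlen_t)i + (R_xlen_t)H * j] : 0.0;
        if (is_background(M, val.data(), H, W, k, N, i, j, r2, lambda)) {
          mask(i, j) = false;
          update_background_pixel(M, val.data(), H, W, k, N, i, j, phi_inv, MD, cur_p);
        } else if (depth &&
                   MD[(R_xlen_t)i + (R_xlen_t)H * j] - cur_p > tau) {
          // ghost: object departed, so the stored proximity exceeds what the
          // sensor now sees; store background and adapt the color model, but
          // keep MD so the excuse survives until the color model has caught up
          mask(i, j) = false;
          ++ghosts;
          update_background_pixel(M, val.data(), H, W, k, N, i, j, phi_inv,
                                  (double*)0, 0.0);
        } else {
          mask(i, j) = true;
        }
      }
    }
    masks[t] = mask;
    ghost_counts[t] = ghosts;
  }
  List out = List::create(_["masks"] = masks,
                          _["ghost_reclassified"] = ghost_counts,
                          _["model"] = model);
  if (depth) out["depth_model"] = depth_model;
  return out;
}

// [[Rcpp::export]]
List cpp_run_vibe(List frames, int n_samples, double radius, int min_matches, int phi) {
  return run_loop(frames, n_samples, radius, min_matches, phi, R_NilValue, 0.0);
}

// [[Rcpp::export]]
List cpp_run_devb(List frames, List prox_frames, int n_samples, double radius,
                  int min_matches, int phi, double tau) {
  return run_loop(frames, n_samples, radius, min_matches, phi, prox_frames, tau);
}

// Tag-survival experiment for the random-subsampling lifespan law: every
// sample of every pixel is tagged at frame 1; each frame each pixel fires the
// 1/phi update coin and, when it fires, a uniformly chosen slot loses its tag
// (that slot's sample was replaced). Isolates the in-place update channel the
// exponential-decay law describes.
// [[Rcpp::export]]
double cpp_lifespan_survival(int height, int width, int n_samples, int phi, int n_frames) {
  R_xlen_t npix = (R_xlen_t)height * width;
  std::vector<char> tag((size_t)(npix * n_samples), 1);
  double phi_inv = 1.0 / phi;
  for (int t = 0; t < n_frames; ++t)
    for (R_xlen_t p = 0; p < npix; ++p)
      if (unif_rand() < phi_inv)
        tag[(size_t)(p * n_samples + rint_below(n_samples))] = 0;
  R_xlen_t alive = 0;
  for (size_t q = 0; q < tag.size(); ++q) alive += tag[q];
  return (double)alive / (double)(npix * n_samples);
}
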