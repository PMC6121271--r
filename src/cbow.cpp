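#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Softmax with max-shift for numerical stability.
static arma::vec softmax_vec(const arma::vec& u) {
  arma::vec e = arma::exp(u - u.max());
  return e / arma::accu(e);
}

// Forward pass for one window: h = mean of context rows of w_in,
// u = w_out^T h, probs = softmax(u).
// [[Rcpp::export]]
arma::vec cbow_forward_cpp(const arma::mat& w_in, const arma::mat& w_out,
                           const IntegerVector& context) {
  arma::vec h(w_in.n_cols, arma::fill::zeros);
  for (int j = 0; j < context.size(); ++j)
    h += w_in.row(context[j] - 1).t();
  h /= (double)context.size();
  return softmax_vec(w_out.t() * h);
}

// Analytic gradients of the cross-entropy loss for one window.
// grad_context is the gradient applied to EACH context row of w_in
// (already divided by the context size); grad_out is d loss / d w_out.
// [[Rcpp::export]]
List cbow_gradients_cpp(const arma::mat& w_in, const arma::mat& w_out,
                        const IntegerVector& context, int target) {
  int n_ctx = context.size();
  arma::vec h(w_in.n_cols, arma::fill::zeros);
  for (int j = 0; j < n_ctx; ++j)
    h += w_in.row(context[j] - 1).t();
  h /= (double)n_ctx;
  arma::vec probs = softmax_vec(w_out.t() * h);
  double loss = -std::log(probs(target - 1));
  arma::vec e = probs;
  e(target - 1) -= 1.0;            // dL/du
  arma::mat grad_out = h * e.t();  // N x V
  arma::vec grad_h = w_out * e;    // N
  arma::vec grad_context = grad_h / (double)n_ctx;
  return List::create(_["loss"] = loss,
                      _["probs"] = probs,
                      _["grad_context"] = grad_context,
                      _["grad_out"] = grad_out);
}

// Full CBOW SGD training loop. Sequences are 1-based vocabulary index
// vectors with filtered tokens already removed; windows are built on the
// fly (context truncated at sequence edges, never crossing sequences),
// visited in corpus order each epoch. Learning rate decays linearly from
// lr0 to lr0 * lr_min_frac across all updates. No randomness here: the
// caller seeds the initial matrices.
// [[Rcpp::export]]
List cbow_train_cpp(const List& corpus, arma::mat w_in, arma::mat w_out,
                    int context_size, int epochs, double lr0,
                    double lr_min_frac) {
  int n_seq = corpus.size();
  long long total_windows = 0;
  std::vector<IntegerVector> seqs(n_seq);
  for (int s = 0; s < n_seq; ++s) {
    seqs[s] = corpus[s];
    int len = seqs[s].size();
    if (len >= 2) total_windows += len;  // single-token sequences yield none
  }
  if (total_windows == 0)
    stop("no training windows: corpus sequences are too short");
  long long total_updates = total_windows * (long long)epochs;
  double lr_min = lr0 * lr_min_frac;

  int N = w_in.n_cols;
  arma::vec h(N), e, grad_h(N);
  NumericVector epoch_loss(epochs);
  long long t = 0;
  for (int ep = 0; ep < epochs; ++ep) {
    double loss_sum = 0.0;
    long long loss_n = 0;
    for (int s = 0; s < n_seq; ++s) {
      const IntegerVector& seq = seqs[s];
      int len = seq.size();
      if (len < 2) continue;
      for (int i = 0; i < len; ++i) {
        int lo = std::max(0, i - context_size);
        int hi = std::min(len - 1, i + context_size);
        int n_ctx = hi - lo + 1 - 1;  // excludes the target itself
        if (n_ctx <= 0) continue;
        double lr = lr0 + (lr_min - lr0) * ((double)t / (double)total_updates);
        ++t;
        h.zeros();
        for (int j = lo; j <= hi; ++j) {
          if (j == i) continue;
          h += w_in.row(seq[j] - 1).t();
        }
        h /= (double)n_ctx;
        arma::vec probs = softmax_vec(w_out.t() * h);
        int tgt = seq[i] - 1;
        double loss = -std::log(probs(tgt));
        if (!std::isfinite(loss))
          stop("divergence: non-finite loss at epoch %d (learning rate %g)",
               ep + 1, lr);
        loss_sum += loss;
        ++loss_n;
        e = probs;
        e(tgt) -= 1.0;
        grad_h = w_out * e;
        w_out -= lr * (h * e.t());
        arma::rowvec upd = (lr / (double)n_ctx) * grad_h.t();
        for (int j = lo; j <= hi; ++j) {
          if (j == i) continue;
          w_in.row(seq[j] - 1) -= upd;
        }
      }
    }
    epoch_loss[ep] = loss_sum / (double)loss_n;
  }
  return List::create(_["w_in"] = w_in, _["w_out"] = w_out,
                      _["epoch_loss"] = epoch_loss);
}
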