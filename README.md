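# wave2vec

Classification of single-channel bio-signal time series (e.g. 1 s EEG
trials) by symbolic encoding and word-embedding machinery, for researchers
who want a signal classifier whose features stay readable end to end.

Instead of feeding raw real-valued series to a neural network, the
pipeline converts each trial into a sentence over a finite symbol
alphabet and classifies the sentence:

1. **Delta encoding** — keep only successive amplitude changes
   δᵢ = xᵢ₊₁ − xᵢ.
2. **Gaussian quantization** — fit N(μ, σ²) to the pooled training
   deltas; cut the central ±2σ mass into equal-probability bins labeled
   `D31 … D01, U00, U01 … U31` (for an encoding base number *baseN* = 64;
   `D` = fall, `U` = rise). Deltas beyond ±2σ are treated as noise and
   absorbed by the outermost bins; the two near-zero bins merge into a
   single `U00` so sensor jitter is not learned.
3. **Wave embedding** — learn a vector for every symbol with a CBOW
   model (predict the center symbol of a sliding window from the average
   of its context symbols' vectors; full softmax, SGD).
4. **Class models** — each class is the vector sum S꜀ of its training
   sequences' token-vector sums; only the direction of S꜀ matters.
5. **Cosine classification** — assign a new trial with vector T to
   argmax꜀ cos(T, S꜀) = T·S꜀ / (‖T‖‖S꜀‖).

Also included: a transparent pattern-probability baseline classifier
(p(c|seq) = Σ O·S·L/G / n over the sequence's n-grams), stratified k-fold
cross-validation with precision/recall/F1, a *baseN* resolution sweep,
similarity-matrix heat maps whose cross-class difference ("XOR") map
pinpoints the class-discriminating wavelet symbols, a seeded two-class
synthetic-signal generator with planted delta-space motifs, and a
command-line front-end (`inst/cli/wave2vec.R`) chaining the stages.

## Worked example

```r
library(wave2vec)

cfg <- synth_config(n_per_class = 50)   # 1 s, 256-sample trials; 3-step
ds  <- generate_dataset(cfg, seed = 1)  # rise vs fall motifs at 4 x noise SD
fit <- wave2vec(ds, base_n = 64, seed = 1)
fit
#> Wave-embedding signal classifier
#>
#> Call:
#>   wave2vec(data = ds, base_n = 64, seed = 1)
#>
#> Encoding: base_n=64 (63 symbols), clip_z=2
#> Embedding: dim=50, window=10, epochs=3, V=63
#> Classes (100 training instances): alcoholic, control

run_cv(ds, k = 5, seed = 1, base_n = 64)
#> k-fold cross-validation (k=5, positive class: alcoholic)
#> Pooled: precision 0.9057, recall 0.9600, F1 0.9320, accuracy 0.9300
#> Counts: tp 48 fp 5 fn 2 tn 45
```

The cross-validation refits the quantizer, the embeddings and the class
models on each fold's training portion and classifies the held-out fold;
the pooled F1 of 0.93 says the planted class structure is recovered almost
perfectly from 1 s of signal. To see *which* wavelet patterns carry the
separation, train one embedding table per class and compare their symbol
similarity matrices:

```r
cmp <- compare_class_models(ds, base_n = 64, seed = 1)
top_divergent_pairs(cmp$difference, k = 3, spec = cmp$quantizer)
#>   symbol_i symbol_j     score    delta_i    delta_j
#> 1      D27      D20 0.1968737 -1.5615803 -0.9937407
#> 2      D30      D23 0.1885906 -1.9833249 -1.2022927
#> 3      D20      U15 0.1868287 -0.9937407  0.7171422
```

Each row is a pair of amplitude-change symbols whose clustering differs
most between the two class models (`delta_*` are the bins' representative
amplitude changes). The large-fall symbols dominating this list are the
signature of the planted falling motif; `render_heatmap()` draws the
matrices and the difference map.

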