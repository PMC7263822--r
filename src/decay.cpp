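#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Stop codons are TAA, TAG, TGA.
static inline bool is_stop(const char* s) {
  return s[0] == 'T' &&
    ((s[1] == 'A' && (s[2] == 'A' || s[2] == 'G')) ||
     (s[1] == 'G' && s[2] == 'A'));
}

// "Intact" = same length as the starting ORF, (optionally) starts with ATG,
// and no stop codon in any complete codon strictly before the final codon of
// the sequence.  A trailing partial codon (length not a multiple of 3) counts
// as the final codon and can never hold a stop; the last complete codon of a
// codon-multiple sequence is the final codon and is allowed to be a stop.
static bool orf_intact(const std::string& s, int L0, bool require_start) {
  if ((int)s.size() != L0) return false;
  if ((int)s.size() < 3) return false;
  if (require_start && !(s[0] == 'A' && s[1] == 'T' && s[2] == 'G'))
    return false;
  int n_complete = (int)s.size() / 3;
  int final_codon = ((int)s.size() + 2) / 3;  // ceiling
  int n_check = std::min(n_complete, final_codon - 1);
  for (int c = 0; c < n_check; ++c)
    if (is_stop(&s[3 * c])) return false;
  return true;
}

// [[Rcpp::export]]
bool cpp_orf_intact(std::string seq, int original_length, bool require_start) {
  return orf_intact(seq, original_length, require_start);
}

static inline int runif_int(int n) {
  // uniform on 0..n-1 using R's RNG
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

// Neutral decay of one ORF replicated n_reps times.  Events are Poisson
// counts per census interval (mean = rate * current_length * generations per
// interval), applied in random order at uniform positions; intactness is
// re-evaluated at each census on the current sequence.  Uses R's global RNG,
// so set.seed() on the R side gives bit-identical trajectories.
// [[Rcpp::export]]
IntegerVector cpp_simulate_decay(std::string orf, int n_intervals,
                                 double gens_per_interval, double sub_rate,
                                 double ins_rate, double del_rate, int n_reps,
                                 bool require_start) {
  const int L0 = (int)orf.size();
  IntegerVector counts(n_intervals + 1);
  counts[0] = n_reps;
  static const char bases[4] = {'A', 'C', 'G', 'T'};

  for (int rep = 0; rep < n_reps; ++rep) {
    std::string s = orf;
    bool dead = false;   // length hit 0: not-intact thereafter
    bool intact = true;
    for (int iv = 1; iv <= n_intervals; ++iv) {
      if (!dead) {
        double Lg = (double)s.size() * gens_per_interval;
        int nsub = (int)R::rpois(sub_rate * Lg);
        int nins = (int)R::rpois(ins_rate * Lg);
        int ndel = (int)R::rpois(del_rate * Lg);
        int ntot = nsub + nins + ndel;
        if (ntot > 0) {
          std::vector<char> ev;
          ev.reserve(ntot);
          for (int k = 0; k < nsub; ++k) ev.push_back(0);
          for (int k = 0; k < nins; ++k) ev.push_back(1);
          for (int k = 0; k < ndel; ++k) ev.push_back(2);
          for (int k = ntot - 1; k > 0; --k)
            std::swap(ev[k], ev[runif_int(k + 1)]);
          for (int k = 0; k < ntot; ++k) {
            int len = (int)s.size();
            if (len == 0) { dead = true; break; }
            int pos = runif_int(len);
            if (ev[k] == 0) {
              char cur = s[pos];
              char alt[3];
              int bi = 0;
              for (int b = 0; b < 4; ++b)
                if (bases[b] != cur) alt[bi++] = bases[b];
              s[pos] = alt[runif_int(3)];
            } else if (ev[k] == 1) {
              s.insert(s.begin() + pos + 1, bases[runif_int(4)]);
            } else {
              s.erase(s.begin() + pos);
              if (s.empty()) { dead = true; break; }
            }
          }
          intact = dead ? false : orf_intact(s, L0, require_start);
        }
        // no events: intact status unchanged since last census
      } else {
        intact = false;
      }
      if (intact) counts[iv]++;
    }
  }
  return counts;
}
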