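#include <Rcpp.h>
#include <string>
#include <cstring>

// Exhaustive-history LZ76 phrase count. Parsing rule: starting at i, extend
// the current phrase while the extension s[i..i+m-1] can be copied from a
// source starting strictly before i (self-overlap allowed, i.e. the
// extension occurs somewhere in s[0..i+m-2]); the first non-copyable
// extension closes the phrase. A final phrase that is still copyable when
// the end of the string is reached counts as one phrase.
// [[Rcpp::export]]
int lz76_phrase_count(const std::string& s) {
    const int n = (int) s.size();
    if (n == 0) return 0;
    const char* p = s.data();
    int i = 0, c = 0;
    while (i < n) {
        int m = 1;
        for (;;) {
            if (i + m - 1 >= n) { // ran off the end while still copyable
                return c + 1;
            }
            bool found = false;
            for (int q = 0; q < i; ++q) {
                if (std::memcmp(p + q, p + i, (size_t) m) == 0) {
                    found = true;
                    break;
                }
            }
            if (!found) break;
            ++m;
        }
        ++c;      // phrase s[i..i+m-1]: longest copyable run plus one new char
        i += m;
    }
    return c;
}
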