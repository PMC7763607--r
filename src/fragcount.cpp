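#include <Rcpp.h>
#include <map>
#include <string>
#include <vector>
#include <algorithm>

// Enumeration of connected induced subgraphs of a heavy-atom molecular graph
// (ESU / "exact subgraph enumeration" scheme: every connected vertex subset of
// size <= max_atoms is visited exactly once), followed by topology
// classification and canonical key construction.
//
// Topologies kept:
//   atom   - single vertex
//   path   - tree with maximum internal degree 2
//   branch - tree with exactly one vertex of degree >= 3 (star with rays)
//   cycle  - induced (chordless) ring, all degrees 2
// Any other induced subgraph (trees with two branch points, fused/bridged
// ring systems) is skipped.
//
// Atom labels are supplied per classification level; labels must not contain
// the structural characters '(', ')', '|' or the bond symbols "-=#:".

namespace {

struct Graph {
  int n;
  std::vector<std::vector<int> > adj;       // neighbour lists
  std::vector<std::vector<char> > bsym;     // bond symbol parallel to adj
};

// bond symbol lookup within a vertex subset
inline char bond_between(const Graph &g, int a, int b) {
  const std::vector<int> &na = g.adj[a];
  for (size_t i = 0; i < na.size(); ++i)
    if (na[i] == b) return g.bsym[a][i];
  return 0;
}

// canonical path key: min(forward, reverse) of label(bond)label... sequence
std::string path_key(const std::vector<std::string> &labs,
                     const std::vector<char> &bonds) {
  std::string fwd, rev;
  int n = (int)labs.size();
  for (int i = 0; i < n; ++i) {
    fwd += labs[i];
    if (i < n - 1) fwd += bonds[i];
  }
  for (int i = n - 1; i >= 0; --i) {
    rev += labs[i];
    if (i > 0) rev += bonds[i - 1];
  }
  return (fwd <= rev) ? fwd : rev;
}

// canonical cycle key: min over all rotations in both directions of the
// alternating label/bond string (closing bond included)
std::string cycle_key(const std::vector<std::string> &labs,
                      const std::vector<char> &bonds) {
  // bonds[i] joins atom i and atom (i+1) mod n
  int n = (int)labs.size();
  std::string best;
  for (int dir = 0; dir < 2; ++dir) {
    for (int start = 0; start < n; ++start) {
      std::string s;
      for (int k = 0; k < n; ++k) {
        int idx, bidx;
        if (dir == 0) {
          idx = (start + k) % n;
          bidx = idx;  // bond to next in forward direction
        } else {
          idx = (start - k % n + n) % n;
          bidx = (idx - 1 + n) % n;  // bond to previous atom
        }
        s += labs[idx];
        s += bonds[bidx];
      }
      if (best.empty() || s < best) best = s;
    }
  }
  return best;
}

// Classify + build canonical body for one vertex subset, at one level.
// Returns empty string when the induced subgraph is not atom/path/branch/cycle.
std::string subset_key(const Graph &g, const std::vector<int> &sub,
                       const std::vector<std::string> &labels) {
  int s = (int)sub.size();
  if (s == 1) return "A|" + labels[sub[0]];

  // induced degrees and edge count
  std::vector<int> pos(g.n, -1);
  for (int i = 0; i < s; ++i) pos[sub[i]] = i;
  std::vector<std::vector<int> > nb(s);
  int m = 0;
  for (int i = 0; i < s; ++i) {
    int v = sub[i];
    for (size_t j = 0; j < g.adj[v].size(); ++j) {
      int u = g.adj[v][j];
      if (pos[u] >= 0) {
        nb[i].push_back(pos[u]);
        ++m;
      }
    }
  }
  m /= 2;

  int maxdeg = 0, n_branch = 0, n_leaf = 0;
  for (int i = 0; i < s; ++i) {
    int d = (int)nb[i].size();
    if (d > maxdeg) maxdeg = d;
    if (d >= 3) ++n_branch;
    if (d == 1) ++n_leaf;
  }

  if (m == s - 1) {  // tree
    if (maxdeg <= 2) {
      // path: walk from one leaf
      int start = 0;
      for (int i = 0; i < s; ++i)
        if (nb[i].size() == 1) { start = i; break; }
      std::vector<std::string> labs;
      std::vector<char> bonds;
      int prev = -1, cur = start;
      for (int k = 0; k < s; ++k) {
        labs.push_back(labels[sub[cur]]);
        int nxt = -1;
        for (size_t j = 0; j < nb[cur].size(); ++j)
          if (nb[cur][j] != prev) nxt = nb[cur][j];
        if (nxt >= 0) {
          bonds.push_back(bond_between(g, sub[cur], sub[nxt]));
          prev = cur;
          cur = nxt;
        }
      }
      return "P|" + path_key(labs, bonds);
    }
    if (n_branch == 1) {
      // branch (spider): center + sorted rays
      int c = 0;
      for (int i = 0; i < s; ++i)
        if ((int)nb[i].size() >= 3) { c = i; break; }
      std::vector<std::string> rays;
      for (size_t j = 0; j < nb[c].size(); ++j) {
        std::string ray;
        int prev = c, cur = nb[c][j];
        ray += bond_between(g, sub[c], sub[cur]);
        while (true) {
          ray += labels[sub[cur]];
          int nxt = -1;
          for (size_t t = 0; t < nb[cur].size(); ++t)
            if (nb[cur][t] != prev) nxt = nb[cur][t];
          if (nxt < 0) break;
          ray += bond_between(g, sub[cur], sub[nxt]);
          prev = cur;
          cur = nxt;
        }
        rays.push_back(ray);
      }
      std::sort(rays.begin(), rays.end());
      std::string key = "B|" + labels[sub[c]];
      for (size_t j = 0; j < rays.size(); ++j) key += "(" + rays[j] + ")";
      return key;
    }
    return "";  // tree with >=2 branch points
  }

  if (m == s && maxdeg == 2 && n_leaf == 0) {
    // induced (chordless) cycle: walk around
    std::vector<std::string> labs;
    std::vector<char> bonds;
    int prev = -1, cur = 0;
    for (int k = 0; k < s; ++k) {
      labs.push_back(labels[sub[cur]]);
      int nxt = (nb[cur][0] != prev) ? nb[cur][0] : nb[cur][1];
      bonds.push_back(bond_between(g, sub[cur], sub[nxt]));
      prev = cur;
      cur = nxt;
    }
    return "R|" + cycle_key(labs, bonds);
  }

  return "";  // fused/bridged system
}

struct Tally {
  std::map<std::string, int> counts;
  const Graph *g;
  const std::vector<std::vector<std::string> > *levels;  // per level: labels
  const std::vector<std::string> *level_tags;
  int max_atoms;

  void emit(const std::vector<int> &sub) {
    for (size_t l = 0; l < levels->size(); ++l) {
      std::string body = subset_key(*g, sub, (*levels)[l]);
      if (!body.empty()) counts[(*level_tags)[l] + "|" + body] += 1;
    }
  }

  // ESU extension step
  void extend(std::vector<int> &sub, std::vector<int> &ext, int root,
              std::vector<char> &in_sub, std::vector<char> &seen) {
    emit(sub);
    if ((int)sub.size() >= max_atoms) return;
    while (!ext.empty()) {
      int w = ext.back();
      ext.pop_back();
      std::vector<int> ext2 = ext;
      std::vector<int> newly;
      for (size_t j = 0; j < g->adj[w].size(); ++j) {
        int u = g->adj[w][j];
        if (u > root && !in_sub[u] && !seen[u]) {
          ext2.push_back(u);
          seen[u] = 1;
          newly.push_back(u);
        }
      }
      sub.push_back(w);
      in_sub[w] = 1;
      extend(sub, ext2, root, in_sub, seen);
      in_sub[w] = 0;
      sub.pop_back();
      for (size_t j = 0; j < newly.size(); ++j) seen[newly[j]] = 0;
    }
  }
};

}  // namespace

// [[Rcpp::export]]
Rcpp::IntegerVector count_fragments_cpp(int n_atoms,
                                        Rcpp::IntegerMatrix bonds,
                                        Rcpp::CharacterVector bond_sym,
                                        Rcpp::List level_labels,
                                        Rcpp::CharacterVector level_tags,
                                        int max_atoms) {
  Graph g;
  g.n = n_atoms;
  g.adj.resize(n_atoms);
  g.bsym.resize(n_atoms);
  for (int e = 0; e < bonds.nrow(); ++e) {
    int a = bonds(e, 0) - 1, b = bonds(e, 1) - 1;
    char sym = Rcpp::as<std::string>(bond_sym[e])[0];
    g.adj[a].push_back(b);
    g.bsym[a].push_back(sym);
    g.adj[b].push_back(a);
    g.bsym[b].push_back(sym);
  }

  std::vector<std::vector<std::string> > levels;
  std::vector<std::string> tags;
  for (int l = 0; l < level_labels.size(); ++l) {
    Rcpp::CharacterVector lv = level_labels[l];
    std::vector<std::string> labs(n_atoms);
    for (int i = 0; i < n_atoms; ++i) labs[i] = Rcpp::as<std::string>(lv[i]);
    levels.push_back(labs);
    tags.push_back(Rcpp::as<std::string>(level_tags[l]));
  }

  Tally t;
  t.g = &g;
  t.levels = &levels;
  t.level_tags = &tags;
  t.max_atoms = max_atoms;

  std::vector<char> in_sub(n_atoms, 0), seen(n_atoms, 0);
  for (int v = 0; v < n_atoms; ++v) {
    std::vector<int> sub;
    sub.push_back(v);
    in_sub[v] = 1;
    std::vector<int> ext;
    std::vector<int> newly;
    for (size_t j = 0; j < g.adj[v].size(); ++j) {
      int u = g.adj[v][j];
      if (u > v) {
        ext.push_back(u);
        seen[u] = 1;
        newly.push_back(u);
      }
    }
    t.extend(sub, ext, v, in_sub, seen);
    in_sub[v] = 0;
    for (size_t j = 0; j < newly.size(); ++j) seen[newly[j]] = 0;
  }

  Rcpp::IntegerVector out(t.counts.size());
  Rcpp::CharacterVector nm(t.counts.size());
  int i = 0;
  for (std::map<std::string, int>::const_iterator it = t.counts.begin();
       it != t.counts.end(); ++it, ++i) {
    nm[i] = it->first;
    out[i] = it->second;
  }
  out.names() = nm;
  return out;
}
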