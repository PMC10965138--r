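#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>

// Photon random walk in a semi-infinite homogeneous medium (z > 0):
// pencil beam normally incident at the origin, Henyey-Greenstein
// scattering, absorption as single-scatter albedo weight attenuation,
// Fresnel partial reflection at the tissue-air interface with escaping
// weight tallied into an annular detector band, time-resolved by total
// path length.  Variance control: a launch-normalized importance window
// (photon value = weight x exp(-mueff x distance-to-detector-ring);
// photons falling below the window survive a roulette with probability
// proportional to their value and are reweighted exactly, so the
// estimator stays unbiased) plus a classic low-weight survival roulette.
// Self-contained xoshiro256++ generator: a given seed reproduces the
// walk bit-identically on any platform.

namespace {
struct Xo {
  uint64_t s[4];
  static uint64_t sm(uint64_t &x){x+=0x9E3779B97f4A7C15ULL;uint64_t z=x;z=(z^(z>>30))*0xBF58476D1CE4E5B9ULL;z=(z^(z>>27))*0x94D049BB133111EBULL;return z^(z>>31);}
  explicit Xo(uint64_t seed){uint64_t x=seed;for(int i=0;i<4;++i)s[i]=sm(x);}
  static uint64_t rotl(uint64_t x,int k){return (x<<k)|(x>>(64-k));}
  uint64_t next(){const uint64_t r=rotl(s[0]+s[3],23)+s[0];const uint64_t t=s[1]<<17;s[2]^=s[0];s[3]^=s[1];s[1]^=s[2];s[0]^=s[3];s[2]^=t;s[3]=rotl(s[3],45);return r;}
  double rp(){return ((next()>>11)+1.0)*(1.0/9007199254740993.0);}
  double ru(){return (next()>>11)*(1.0/9007199254740992.0);}
};
}

// [[Rcpp::export]]
Rcpp::List mc_transport_cpp(double mua, double musp, double g, double nr,
                 double rmin, double rmax, double bin_ns, double tmax_ns,
                 double np, double seed,
                 double vthr_rel, double pfloor, int check_every,
                 double wmin) {
  const double mus = musp/(1.0-g);
  const double mut = mus + mua;
  const double albedo = mus/mut;
  const double v = 299.792458/nr;
  const int nb = (int)std::ceil(tmax_ns/bin_ns);
  const double Lmax = v*tmax_ns;
  const double rho_mid = 0.5*(rmin+rmax);
  const double mueff = std::sqrt(3.0*mua*(mua+musp));
  const double vthr = vthr_rel * std::exp(-mueff*rho_mid);
  // Fresnel internal reflectance lookup on cos(theta_i) in [0,1]
  const int NF = 2048;
  std::vector<double> ftab(NF+1);
  for (int i=0;i<=NF;++i){
    double ci = (double)i/NF;
    double st2 = nr*nr*(1.0-ci*ci);
    if (st2 >= 1.0) ftab[i]=1.0;
    else {
      double ct = std::sqrt(1.0-st2);
      double rs=(nr*ci-ct)/(nr*ci+ct);
      double rp=(nr*ct-ci)/(nr*ct+ci);
      ftab[i]=0.5*(rs*rs+rp*rp);
    }
  }
  Rcpp::NumericVector hist(nb);
  double *h = hist.begin();
  Xo rng((uint64_t)seed);
  double det=0, nev=0, steps=0, totesc=0, sumsq=0;
  const uint64_t N=(uint64_t)np;
  for(uint64_t ip=0; ip<N; ++ip){
    double x=0,y=0,z=0,ux=0,uy=0,uz=1,w=1,L=0;
    bool alive=true;
    int cchk=check_every;
    while(alive){
      double s=-std::log(rng.rp())/mut;
      while(s>0){
        if(uz<0){
          double sb=-z/uz;
          if(sb<=s){
            x+=ux*sb; y+=uy*sb; z=0;
            L+=sb; s-=sb;
            double ci=-uz;
            double fi = ci*NF;
            int i0 = (int)fi;
            double R = ftab[i0] + (fi-i0)*(ftab[i0+1<=NF?i0+1:NF]-ftab[i0]);
            double esc=w*(1.0-R);
            if(esc>0){
              totesc+=esc;
              double r2d=x*x+y*y;
              if(r2d>=rmin*rmin && r2d<rmax*rmax){
                double t=L/v;
                if(t<tmax_ns){
                  int ib=(int)(t/bin_ns); if(ib>=nb) ib=nb-1;
                  h[ib]+=esc; det+=esc; nev+=1; sumsq+=esc*esc;
                }
              }
            }
            w*=R; uz=-uz;
            continue;
          }
        }
        x+=ux*s; y+=uy*s; z+=uz*s;
        L+=s; s=0;
      }
      if(L>Lmax) break;
      w*=albedo;
      steps+=1;
      double f=(1.0-g*g)/(1.0-g+2.0*g*rng.ru());
      double ct=(1.0+g*g-f*f)/(2.0*g);
      if(ct>1)ct=1; else if(ct<-1)ct=-1;
      double st=std::sqrt(1.0-ct*ct);
      double a,b,d2;
      do { a=2.0*rng.ru()-1.0; b=2.0*rng.ru()-1.0; d2=a*a+b*b; } while(d2>=1.0||d2==0.0);
      double inv=1.0/d2;
      double cp=(a*a-b*b)*inv, sp=2.0*a*b*inv;
      if(std::fabs(uz)>0.99999){
        ux=st*cp; uy=st*sp; uz=ct*(uz>=0?1.0:-1.0);
      } else {
        double den=std::sqrt(1.0-uz*uz);
        double nux=st*(ux*uz*cp-uy*sp)/den+ux*ct;
        double nuy=st*(uy*uz*cp+ux*sp)/den+uy*ct;
        double nuz=-st*cp*den+uz*ct;
        ux=nux; uy=nuy; uz=nuz;
      }
      if(--cchk<=0){
        cchk=check_every;
        double r=std::sqrt(x*x+y*y);
        double dr=r-rho_mid;
        double dmin2=dr*dr+z*z;
        double V=w*std::exp(-mueff*std::sqrt(dmin2));
        if(V<vthr){
          double p=V/vthr; if(p<pfloor)p=pfloor;
          if(rng.ru()<p) w/=p; else { alive=false; continue; }
        }
      }
      if(w<wmin){
        if(rng.ru()<0.1) w*=10.0; else alive=false;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("hist")=hist, Rcpp::Named("det")=det,
                            Rcpp::Named("nev")=nev, Rcpp::Named("steps")=steps,
                            Rcpp::Named("totesc")=totesc,
                            Rcpp::Named("sumsq")=sumsq);
}
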