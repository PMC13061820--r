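/* Large activation tensors are allocated and freed once per layer per
   batch.  glibc serves >128 KB requests with mmap/munmap, which makes
   every training step pay page-zeroing costs; raising the mmap threshold
   keeps these buffers on the heap where they are reused. */
#ifdef __GLIBC__
#include <malloc.h>
__attribute__((constructor)) static void sononet_malloc_init(void) {
  mallopt(M_MMAP_THRESHOLD, 64 * 1024 * 1024);
  mallopt(M_TRIM_THRESHOLD, 256 * 1024 * 1024);
}
#endif
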