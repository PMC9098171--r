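# Build with the system toolchain. The conda-packaged cross compiler was
# built against a newer glibc than the host runtime provides, so shared
# objects it produces cannot be loaded by this R. The host g++/gcc link
# against the host glibc and against R via R_HOME as usual. "override" is
# required because this file is included before Makeconf.
override CC = gcc
override CXX = g++
override CXX11 = g++
override CXX14 = g++
override CXX17 = g++
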