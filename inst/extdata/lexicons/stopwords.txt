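a
an
and
are
as
at
be
but
by
for
from
has
he
in
is
it
its
of
on
or
she
that
the
to
was
were
will
with
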