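a
an
and
are
as
at
be
been
both
but
by
for
from
had
has
have
he
her
his
if
in
into
is
it
its
no
not
of
on
or
s
she
such
t
that
the
their
then
there
these
they
this
those
to
was
were
which
while
who
will
with
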