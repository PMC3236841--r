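# Default stoplist: common English function words discarded during
# tokenization (same role as the classic SMART stoplist).
a
about
above
after
again
against
all
also
although
among
an
and
any
are
as
at
be
because
been
before
being
below
between
both
but
by
can
cannot
could
did
do
does
doing
down
during
each
either
few
for
from
further
had
has
have
having
he
her
here
hers
him
his
how
however
i
if
in
into
is
it
its
itself
may
me
might
more
most
must
my
neither
no
nor
not
of
off
on
once
only
or
other
our
ours
out
over
own
per
she
should
since
so
some
such
than
that
the
their
theirs
them
then
there
these
they
this
those
through
thus
to
too
under
until
up
upon
us
very
was
we
were
what
when
where
whether
which
while
who
whom
why
will
with
within
without
would
you
your
yours
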